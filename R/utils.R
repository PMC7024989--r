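# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generator calls do not perturb user scripts.
withr_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Round half-up to the nearest integer (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)
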