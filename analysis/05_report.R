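#!/usr/bin/env Rscript
# Stage 5: assemble the investment guide posts.
#
# Runs the whole pipeline in one pass (identical, by seed determinism, to
# stages 1-4) and writes the guide-post table by income group and maturity
# category: additional cost, per-capita spending including the
# current-plus-additional total, workforce densities, outpatient visits,
# deaths averted and life-expectancy gains.

library(phcguideposts)

seed <- as.integer(Sys.getenv("PHC_SEED", "1"))
res <- run_pipeline(pipeline_config(seed = seed), out_dir = "results/05_report")

gp <- res$guideposts
m1 <- gp[gp$measure_id == "m1" &
           gp$group %in% c("low", "lower_middle", "upper_middle", "all"), ]
cols <- c("group", "additional_per_capita", "additional_recurrent_per_capita",
          "current_phc_per_capita", "total_recurrent_per_capita_2030",
          "workers_per_1000_current", "workers_per_1000_2030",
          "visits_per_capita_2030", "le_gain_years")
message("measure-1 guide posts by income group (US$2014 per capita):")
print(as.data.frame(m1[, cols]), digits = 3)

message("annual additional cost, billion US$2014 (capital + recurrent):")
print(round(tapply(res$ledger$amount, res$ledger$measure_id, sum) / 11 / 1e9, 1))
message("full table bundle written to results/05_report")
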