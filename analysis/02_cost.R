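#!/usr/bin/env Rscript
# Stage 2: incremental PHC costs 2020-2030 under the three measures.
#
# Runs the ingredients engine for every country and measure and writes the
# country-year-component ledger plus component and measure totals.

library(phcguideposts)
suppressPackageStartupMessages(library(dplyr))

seed <- as.integer(Sys.getenv("PHC_SEED", "1"))
out <- "results/02_costs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

catalog <- generate_catalog(seed = seed)
countries <- generate_countries(generator_config(seed = seed),
                                catalog = catalog)

ledger <- purrr::map_dfr(countries, function(co) {
  purrr::map_dfr(c("m1", "m2", "m3"), function(m)
    cost_country(co, catalog, m))
})
utils::write.table(ledger, file.path(out, "cost_ledger.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

by_measure <- aggregate_costs(ledger, measure_id, annual_average = TRUE)
by_comp <- aggregate_costs(ledger, measure_id, component) |>
  group_by(measure_id) |>
  mutate(share = amount / sum(amount)) |>
  ungroup()
utils::write.table(by_comp, file.path(out, "cost_components.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

message("annual additional cost, billion US$2014:")
print(mutate(by_measure, billion = round(amount / 1e9, 1))[, c("measure_id",
                                                               "billion")])
top <- by_comp |> filter(measure_id == "m1") |> arrange(desc(share))
message("largest measure-1 components: ",
        paste(head(top$component, 3), collapse = ", "),
        " (", paste(round(100 * head(top$share, 3)), collapse = "/"),
        "% of cost)")
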