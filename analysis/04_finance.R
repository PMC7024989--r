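#!/usr/bin/env Rscript
# Stage 4: financing scenarios and PHC funding gaps.
#
# Projects health expenditure (% of GDP) under business-as-usual and the
# +1/+2 percentage-point paths, then counts countries whose measure-1
# incremental cost exceeds their incremental health funds in 2030.

library(phcguideposts)
suppressPackageStartupMessages(library(dplyr))

seed <- as.integer(Sys.getenv("PHC_SEED", "1"))
out <- "results/04_financing"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

catalog <- generate_catalog(seed = seed)
countries <- generate_countries(generator_config(seed = seed),
                                catalog = catalog)

# 2030 incremental cost is compared with 2030 incremental funds
costs <- vapply(countries, function(co) {
  led <- cost_country(co, catalog, "m1")
  sum(led$amount[led$year == 2030])
}, numeric(1))
names(costs) <- vapply(countries, `[[`, "", "country_id")

financing <- purrr::map_dfr(countries, function(co)
  purrr::map_dfr(c("bau", "progress1", "ambitious2"), project_che,
                 country = co))
utils::write.table(financing, file.path(out, "financing.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

gap_counts <- purrr::map_dfr(c("bau", "progress1", "ambitious2"),
  function(sc) {
    projs <- lapply(countries, project_che, scenario = sc)
    tibble::tibble(scenario = sc,
                   n_gap = count_gap_countries(projs, costs, 2030))
  })
utils::write.table(gap_counts, file.path(out, "gap_counts.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

avg_pct <- financing |>
  filter(scenario == "bau", year %in% c(2020, 2030)) |>
  group_by(year) |> summarise(mean_pct = mean(che_pct_gdp))
message("mean health expenditure, % of GDP (business as usual):")
print(as.data.frame(avg_pct))
message("countries with a 2030 funding gap, of ", length(countries), ":")
print(as.data.frame(gap_counts))
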