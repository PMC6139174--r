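#!/usr/bin/env Rscript

# Deterministic sensitivity analyses: the +/-25% tornado on incremental cost
# and incremental QALYs, the equal-discounting (3.5%/3.5%) scenario, the
# Portuguese ipilimumab price scenario, and the TIL threshold prices.
# Writes results/tornado.csv, results/scenarios.json,
# results/threshold_prices.json.

suppressPackageStartupMessages(library(tilcea))
dir.create("results", showWarnings = FALSE)

settings <- model_settings()
tbl <- builtin_table1()

tor <- suppressWarnings(one_way_sa(tbl, settings, fraction = 0.25))
write.csv(tor, "results/tornado.csv", row.names = FALSE)
cat("Top 5 drivers of incremental cost:\n")
print(tor[1:5, c("name", "range_cost")], row.names = FALSE)
tor_q <- suppressWarnings(one_way_sa(tbl, settings, outcome = "qaly"))
cat("Top 5 drivers of incremental QALYs:\n")
print(tor_q[1:5, c("name", "range_qaly")], row.names = FALSE)

sc_disc <- scenario(tbl, settings,
                    setting_overrides = list(discount_costs = 0.035,
                                             discount_effects = 0.035))
cat("\nEqual discounting at 3.5%:\n"); print(sc_disc)
sc_pt <- scenario(tbl, settings, param_overrides = list(ipi_cost_drug = 59500))
cat("Portuguese ipilimumab drug price (59,500 EUR):\n"); print(sc_pt)

summarize <- function(bc) list(til = bc$til, ipi = bc$ipi,
                               incremental = unclass(bc$incremental))
jsonlite::write_json(
  list(equal_discounting_3_5 = summarize(sc_disc),
       ipilimumab_price_portugal = summarize(sc_pt)),
  "results/scenarios.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

prices <- list(
  dominance = threshold_price(tbl, settings, "dominance"),
  icer_80000 = threshold_price(tbl, settings, "icer", wtp = 80000),
  dominance_no_rerouting = threshold_price(tbl, settings, "dominance",
                                           failure_rerouting = FALSE))
cat(sprintf("TIL price keeping dominance:       %s EUR\n",
            format(round(prices$dominance), big.mark = ",")))
cat(sprintf("TIL price keeping ICER <= 80,000:  %s EUR\n",
            format(round(prices$icer_80000), big.mark = ",")))
jsonlite::write_json(prices, "results/threshold_prices.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/tornado.csv, results/scenarios.json, results/threshold_prices.json\n")
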