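#!/usr/bin/env Rscript

# Value of information: per-person EVPI at the 80,000 EUR/QALY ceiling ratio
# and its scaling to the beneficial population (400 eligible advanced
# melanoma patients per year over a 10-year decision horizon, discounted at
# 4%). Reuses the PSA seed of analysis/03_psa.R. Writes results/evpi.json
# and an EVPI-versus-threshold curve.

suppressPackageStartupMessages(library(tilcea))
dir.create("results", showWarnings = FALSE)

settings <- model_settings()
psa <- run_psa(builtin_table1(), settings, seed = 2026)

res <- evpi(psa, settings)
print(res)
jsonlite::write_json(unclass(res), "results/evpi.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

curve <- data.frame(
  wtp = settings$wtp_grid,
  per_person = vapply(settings$wtp_grid,
                      function(l) evpi_per_person(psa, l), numeric(1)))
curve$population <- curve$per_person * res$effective_population
write.csv(curve, "results/evpi_curve.csv", row.names = FALSE)
cat("Wrote results/evpi.json, results/evpi_curve.csv\n")
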