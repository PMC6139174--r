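#!/usr/bin/env Rscript

# Evidence pooling for the TIL arm: the two phase-II trials reporting 1-year
# overall survival (7/20 and 20/31) and progression-free survival (3/20 and
# 10/31) are combined by fixed-effect inverse-variance pooling on the logit
# scale. Writes results/pooled_survival.csv.

suppressPackageStartupMessages(library(tilcea))
dir.create("results", showWarnings = FALSE)

studies <- data.frame(
  study = c("besser", "radvanyi"),
  os_events = c(7, 20), pfs_events = c(3, 10), n = c(20, 31)
)

rows <- list()
for (outcome in c("os", "pfs")) {
  events <- studies[[paste0(outcome, "_events")]]
  for (i in seq_len(nrow(studies))) {
    ci <- proportion_logit_ci(events[i], studies$n[i])
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = outcome, source = studies$study[i], k = 1L,
      mean = ci$mean, ci_low = ci$ci_low, ci_high = ci$ci_high)
  }
  pooled <- pool_fixed(events, studies$n)
  rows[[length(rows) + 1L]] <- data.frame(
    outcome = outcome, source = "pooled", k = pooled$k,
    mean = pooled$mean, ci_low = pooled$ci_low, ci_high = pooled$ci_high)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/pooled_survival.csv", row.names = FALSE)

cat("Pooled 1-year TIL survival (fixed effect, logit scale):\n")
for (outcome in c("os", "pfs")) {
  p <- tab[tab$outcome == outcome & tab$source == "pooled", ]
  cat(sprintf("  %-4s %.3f (95%% CI %.3f-%.3f)\n",
              toupper(outcome), p$mean, p$ci_low, p$ci_high))
}
cat("Wrote results/pooled_survival.csv\n")
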