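# Construct a psa_results object from incremental effect/cost pairs, for
# tests that need a hand-built CE-plane cloud. QALYs are placed on the TIL
# arm, costs split so that cost_til - cost_ipi = d_cost.
fake_psa <- function(d_qaly, d_cost, base_cost = 1e5) {
  structure(
    list(samples = data.frame(
      ly_til = 1, qaly_til = d_qaly, cost_til = base_cost + d_cost,
      ly_ipi = 1, qaly_ipi = 0, cost_ipi = base_cost),
      iterations = length(d_qaly), seed = NULL,
      rejections = c(til = 0L, ipi = 0L)),
    class = "psa_results")
}

# Independent brute-force fixed-effect pooling on the logit scale: written
# from the definition (weighted mean with inverse-variance weights) without
# reusing the package's vectorized path.
brute_pool_logit <- function(events, n) {
  num <- 0
  den <- 0
  for (i in seq_along(events)) {
    y <- log((events[i] / n[i]) / (1 - events[i] / n[i]))
    v <- 1 / events[i] + 1 / (n[i] - events[i])
    num <- num + y / v
    den <- den + 1 / v
  }
  c(mean = num / den, se = sqrt(1 / den))
}
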