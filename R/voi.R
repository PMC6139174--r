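#' Per-person expected value of perfect information
#'
#' The expected gain, in EUR per patient, from resolving all parameter
#' uncertainty before choosing a strategy: the mean over PSA iterations of
#' the best achievable net monetary benefit, minus the net monetary benefit
#' of the strategy that is best on average. Tiny negative values (Monte Carlo
#' noise only; the quantity is non-negative by construction with exact
#' arithmetic) are clipped to zero with a message.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay threshold (EUR/QALY), default 80000.
#' @return Per-person EVPI in EUR.
#' @examples
#' psa <- run_psa(iterations = 500, seed = 1)
#' evpi_per_person(psa, wtp = 80000)
#' @export
evpi_per_person <- function(psa, wtp = 80000) {
  .check_psa(psa)
  s <- psa$samples
  nmb_til <- nmb(s$qaly_til, s$cost_til, wtp)
  nmb_ipi <- nmb(s$qaly_ipi, s$cost_ipi, wtp)
  v <- mean(pmax(nmb_til, nmb_ipi)) - max(mean(nmb_til), mean(nmb_ipi))
  if (v < 0) {
    message("per-person EVPI of ", signif(v, 3), " clipped to 0.")
    v <- 0
  }
  v
}

#' Scale per-person EVPI to the beneficial population
#'
#' The effective population is the discounted stream of incident patients
#' over the decision horizon:
#' `sum over t = 0..years-1 of incident_per_year / (1 + discount)^t`.
#'
#' @param per_person Per-person EVPI in EUR.
#' @param incident_per_year Patients per year who would benefit from the
#'   decision (default 400).
#' @param years Decision horizon in years (default 10).
#' @param discount Annual discount rate (default 0.04).
#' @param wtp Threshold at which `per_person` was computed (for reporting).
#' @return A list of class `evpi_result`: `wtp`, `per_person`,
#'   `effective_population`, `population_evpi`.
#' @export
population_evpi <- function(per_person, incident_per_year = 400, years = 10,
                            discount = 0.04, wtp = 80000) {
  if (per_person < 0 || incident_per_year < 0 || years < 0 || discount < 0) {
    stop("all arguments must be non-negative.")
  }
  eff_pop <- if (years == 0) 0 else {
    sum(incident_per_year * (1 + discount)^-(0:(years - 1)))
  }
  structure(list(wtp = wtp, per_person = per_person,
                 effective_population = eff_pop,
                 population_evpi = per_person * eff_pop),
            class = "evpi_result")
}

#' Expected value of perfect information from PSA samples
#'
#' Convenience wrapper combining [evpi_per_person()] and [population_evpi()]
#' using the value-of-information settings.
#'
#' @param psa A [run_psa()] result.
#' @param settings A [model_settings()] object supplying `wtp_threshold`,
#'   `voi_population`, `voi_years`, `voi_discount`.
#' @return An `evpi_result` (see [population_evpi()]).
#' @export
evpi <- function(psa, settings = model_settings()) {
  population_evpi(
    per_person = evpi_per_person(psa, wtp = settings$wtp_threshold),
    incident_per_year = settings$voi_population,
    years = settings$voi_years,
    discount = settings$voi_discount,
    wtp = settings$wtp_threshold
  )
}

#' @export
print.evpi_result <- function(x, ...) {
  cat(sprintf("EVPI at %s EUR/QALY:\n", format(x$wtp, big.mark = ",")))
  cat(sprintf("  per person:           %s EUR\n",
              format(round(x$per_person), big.mark = ",")))
  cat(sprintf("  effective population: %s persons (discounted)\n",
              format(round(x$effective_population), big.mark = ",")))
  cat(sprintf("  population EVPI:      %.2f M EUR\n", x$population_evpi / 1e6))
  invisible(x)
}
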