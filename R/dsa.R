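#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter in turn to `mean * (1 - fraction)` and
#' `mean * (1 + fraction)`, holding all others at their base-case means, and
#' records the incremental cost and incremental QALYs of TIL versus
#' ipilimumab at each extreme. Probabilities and utilities that would exceed
#' 1 after scaling are capped at 1 with a warning.
#'
#' @param tbl A parameter table (default [builtin_table1()]).
#' @param settings A [model_settings()] object.
#' @param fraction Relative variation, in (0, 1); default 0.25.
#' @param outcome Outcome whose range orders the tornado: `"cost"`
#'   (incremental cost, default) or `"qaly"` (incremental QALYs).
#' @return A data frame, one row per parameter, sorted by decreasing range on
#'   the chosen outcome: `name`, `strategy`, `group`, `low`, `high` (input
#'   values), `d_cost_low`, `d_cost_high`, `d_qaly_low`, `d_qaly_high`,
#'   `range_cost`, `range_qaly`.
#' @export
one_way_sa <- function(tbl = builtin_table1(), settings = model_settings(),
                       fraction = 0.25, outcome = c("cost", "qaly")) {
  outcome <- match.arg(outcome)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1).")
  validate_parameter_table(tbl)
  means <- parameter_means(tbl)
  cols <- .param_cols(tbl)
  is_prob <- tbl$group %in% c("survival", "utility", "disutility",
                              "ae_likelihood", "failure")
  capped <- character(0)
  run_at <- function(col, value) {
    m <- means
    m[[col]] <- value
    ev <- evaluate_cohort(m, settings)
    c(d_cost = ev$cost_til - ev$cost_ipi, d_qaly = ev$qaly_til - ev$qaly_ipi)
  }
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    lo <- tbl$mean[i] * (1 - fraction)
    hi <- tbl$mean[i] * (1 + fraction)
    if (is_prob[i] && hi > 1) {
      capped <<- c(capped, cols[i])
      hi <- 1
    }
    r_lo <- run_at(cols[i], lo)
    r_hi <- run_at(cols[i], hi)
    data.frame(name = cols[i], strategy = tbl$strategy[i], group = tbl$group[i],
               low = lo, high = hi,
               d_cost_low = r_lo[["d_cost"]], d_cost_high = r_hi[["d_cost"]],
               d_qaly_low = r_lo[["d_qaly"]], d_qaly_high = r_hi[["d_qaly"]])
  })
  out <- do.call(rbind, rows)
  out$range_cost <- abs(out$d_cost_high - out$d_cost_low)
  out$range_qaly <- abs(out$d_qaly_high - out$d_qaly_low)
  if (length(capped)) {
    warning("capped at 1 after +", 100 * fraction, "% scaling: ",
            paste(capped, collapse = ", "))
  }
  out <- out[order(-out[[paste0("range_", outcome)]]), ]
  rownames(out) <- NULL
  out
}

#' Scenario analysis
#'
#' Re-runs the deterministic base case under named parameter and/or setting
#' overrides. Parameter names use the draw-column layout of
#' [parameter_means()] (`til_`/`ipi_` prefix for strategy parameters, bare
#' name for shared ones); unknown names are an error.
#'
#' @param tbl A parameter table (default [builtin_table1()]).
#' @param settings A [model_settings()] object.
#' @param param_overrides Named list of parameter means to replace, e.g.
#'   `list(ipi_cost_drug = 59500)`.
#' @param setting_overrides Named list of [model_settings()] fields to
#'   replace, e.g. `list(discount_costs = 0.035, discount_effects = 0.035)`.
#' @return A `cea_base_case` (see [base_case()]).
#' @examples
#' scenario(setting_overrides = list(discount_costs = 0.035,
#'                                   discount_effects = 0.035))
#' @export
scenario <- function(tbl = builtin_table1(), settings = model_settings(),
                     param_overrides = list(), setting_overrides = list()) {
  validate_parameter_table(tbl)
  cols <- .param_cols(tbl)
  for (nm in names(param_overrides)) {
    i <- which(cols == nm)
    if (length(i) != 1L) stop("unknown parameter override: ", nm)
    tbl$mean[i] <- param_overrides[[nm]]
    if (tbl$se[i] == 0) tbl$distribution[i] <- "fixed"
  }
  if (length(setting_overrides)) {
    unknown <- setdiff(names(setting_overrides), names(unclass(settings)))
    if (length(unknown)) stop("unknown setting override(s): ",
                              paste(unknown, collapse = ", "))
    args <- utils::modifyList(unclass(settings), setting_overrides)
    settings <- do.call(model_settings, args)
  }
  base_case(tbl, settings)
}

#' Threshold search on the TIL price
#'
#' Finds, by bisection to a EUR 1 tolerance, the TIL per-treatment price at
#' the boundary of a criterion: `"dominance"` (incremental cost of TIL
#' versus ipilimumab equal to zero) or `"icer"` (incremental cost equal to
#' `wtp` times the incremental QALYs). The TIL production cost is held at
#' its table value while the charged price varies; with
#' `failure_rerouting = TRUE` (default) lab failures and pre-infusion
#' progressors are costed through [til_expected_treatment_cost()], otherwise
#' every patient is charged the price alone.
#'
#' Total cost is affine in the price, so the bisection target is unique when
#' the criterion function changes sign over the bracket; if it does not, an
#' error reports the bracket values.
#'
#' @param tbl A parameter table (default [builtin_table1()]).
#' @param settings A [model_settings()] object.
#' @param criterion `"dominance"` or `"icer"`.
#' @param wtp Willingness-to-pay threshold for the `"icer"` criterion
#'   (default `settings$wtp_threshold`).
#' @param bracket Search interval for the price in EUR
#'   (default `c(0, 500000)`).
#' @param failure_rerouting Cost failures through the composite TIL costing
#'   rule (default `TRUE`).
#' @param tol Bisection tolerance in EUR (default 1).
#' @return The threshold price in EUR.
#' @export
threshold_price <- function(tbl = builtin_table1(), settings = model_settings(),
                            criterion = c("dominance", "icer"),
                            wtp = settings$wtp_threshold,
                            bracket = c(0, 500000),
                            failure_rerouting = TRUE, tol = 1) {
  criterion <- match.arg(criterion)
  if (length(bracket) != 2L || bracket[1] >= bracket[2]) {
    stop("`bracket` must be an increasing interval c(lo, hi).")
  }
  validate_parameter_table(tbl)
  m <- parameter_means(tbl)
  ev <- evaluate_cohort(m, settings)
  d_qaly <- ev$qaly_til - ev$qaly_ipi
  ipi_total <- .ipi_treatment_cost(m)
  til_cost_at <- function(price) {
    treat <- if (failure_rerouting) {
      til_expected_treatment_cost(price, m$til_cost_production, ipi_total,
                                  m$til_f_lab, m$til_f_progression)
    } else {
      price
    }
    treat + ev$state_cost_til
  }
  g <- function(price) {
    d_cost <- til_cost_at(price) - ev$cost_ipi
    if (criterion == "dominance") d_cost else d_cost - wtp * d_qaly
  }
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- g(lo); g_hi <- g(hi)
  if (sign(g_lo) == sign(g_hi)) {
    stop(sprintf(
      "criterion '%s' does not change sign over the bracket [%g, %g] (values %.2f, %.2f).",
      criterion, lo, hi, g_lo, g_hi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(g_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
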