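#' Build the three-state annual transition matrix
#'
#' States are stable disease, progressive disease, and death. The annual
#' probability of surviving the year is `os_1y` from both alive states;
#' patients in stable disease remain stable with probability `pfs_1y`,
#' progress with probability `os_1y - pfs_1y`, and die with probability
#' `1 - os_1y`. Death is absorbing.
#'
#' @param os_1y Annual overall-survival probability.
#' @param pfs_1y Annual progression-free-survival probability
#'   (`pfs_1y <= os_1y`).
#' @return A 3x3 row-stochastic matrix with dimnames
#'   `c("stable", "progressive", "dead")`.
#' @examples
#' build_transition_matrix(0.366, 0.175)
#' @export
build_transition_matrix <- function(os_1y, pfs_1y) {
  if (length(os_1y) != 1L || length(pfs_1y) != 1L) stop("scalar probabilities expected.")
  if (os_1y < 0 || os_1y > 1 || pfs_1y < 0 || pfs_1y > 1) {
    stop("probabilities must lie in [0, 1].")
  }
  if (pfs_1y > os_1y) stop("`pfs_1y` must not exceed `os_1y`.")
  m <- matrix(c(pfs_1y, os_1y - pfs_1y, 1 - os_1y,
                0,      os_1y,          1 - os_1y,
                0,      0,              1),
              nrow = 3, byrow = TRUE, dimnames = list(.states, .states))
  m
}

#' Run the cohort trace
#'
#' Propagates a cohort that starts entirely in stable disease through the
#' transition matrix for `horizon` cycles.
#'
#' @param matrix A 3x3 row-stochastic transition matrix
#'   (see [build_transition_matrix()]).
#' @param horizon Number of cycles (>= 1).
#' @return A data frame with columns `cycle` (0..horizon), `stable`,
#'   `progressive`, `dead`; each row sums to 1.
#' @examples
#' run_trace(build_transition_matrix(0.366, 0.175), 10)
#' @export
run_trace <- function(matrix, horizon) {
  if (!is.matrix(matrix) || any(dim(matrix) != 3) ||
      any(abs(rowSums(matrix) - 1) > 1e-12) || any(matrix < 0) || any(matrix > 1)) {
    stop("`matrix` must be a 3x3 row-stochastic matrix.")
  }
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("`horizon` must be at least 1.")
  occ <- matrix(0, nrow = horizon + 1L, ncol = 3, dimnames = list(NULL, .states))
  occ[1L, ] <- c(1, 0, 0)
  for (t in seq_len(horizon)) occ[t + 1L, ] <- occ[t, ] %*% matrix
  data.frame(cycle = 0:horizon, occ)
}

#' Expected adverse-event management cost
#'
#' Likelihood-weighted sum of per-event management costs, incurred once with
#' treatment.
#'
#' @param likelihood Per-event occurrence probabilities.
#' @param cost Per-event management costs (EUR), same length.
#' @return Expected cost in EUR.
#' @examples
#' expected_ae_cost(c(0.07, 0.06, 0.06, 0.04, 0.10, 0.03),
#'                  c(198, 580, 1115, 100, 7680, 898))  # 914.50
#' @export
expected_ae_cost <- function(likelihood, cost) {
  if (length(likelihood) != length(cost)) stop("`likelihood` and `cost` must match in length.")
  if (length(likelihood) == 0L) return(0)
  if (any(likelihood < 0) || any(likelihood > 1)) stop("likelihoods must lie in [0, 1].")
  if (any(cost < 0)) stop("costs must be non-negative.")
  sum(likelihood * cost)
}

#' Expected adverse-event disutility
#'
#' Likelihood-weighted sum of utility decrements, scaled by the duration (in
#' years) over which the decrements apply. In the cohort model this QALY loss
#' is applied once, at cycle 1, with effect discounting.
#'
#' @param likelihood Per-event occurrence probabilities.
#' @param decrement Per-event utility decrements, same length.
#' @param duration Duration of the decrement in years.
#' @return Expected QALY decrement.
#' @export
expected_ae_disutility <- function(likelihood, decrement, duration) {
  if (length(likelihood) != length(decrement)) {
    stop("`likelihood` and `decrement` must match in length.")
  }
  if (duration < 0) stop("`duration` must be non-negative.")
  if (length(likelihood) == 0L) return(0)
  if (any(likelihood < 0) || any(likelihood > 1) ||
      any(decrement < 0) || any(decrement > 1)) {
    stop("likelihoods and decrements must lie in [0, 1].")
  }
  sum(likelihood * decrement) * duration
}

#' Expected TIL treatment cost under production failure and early progression
#'
#' A fraction `f_lab` of intended TIL patients experience a laboratory
#' production failure and a fraction `f_prog` progress between consent and
#' infusion; both groups are treated with ipilimumab instead. Lab failures
#' are charged the TIL production cost only (plus the full ipilimumab
#' treatment); pre-infusion progressors are charged the full TIL price (plus
#' the full ipilimumab treatment); the remainder pay the TIL price alone.
#'
#' @param til_price Full TIL price per treatment (EUR).
#' @param production_cost TIL production component of the price (EUR).
#' @param ipi_total Total ipilimumab treatment cost (EUR).
#' @param f_lab Fraction with laboratory production failure.
#' @param f_prog Fraction progressing before infusion.
#' @return Expected per-patient treatment cost (EUR). Vectorized.
#' @examples
#' til_expected_treatment_cost(62000, 35500, 91487.5, 0.10, 0.10)  # 77647.50
#' @export
til_expected_treatment_cost <- function(til_price, production_cost, ipi_total,
                                        f_lab, f_prog) {
  if (any(f_lab < 0) || any(f_lab > 1) || any(f_prog < 0) || any(f_prog > 1) ||
      any(f_lab + f_prog > 1)) {
    stop("failure fractions must lie in [0, 1] with f_lab + f_prog <= 1.")
  }
  (1 - f_lab - f_prog) * til_price +
    f_lab * (production_cost + ipi_total) +
    f_prog * (til_price + ipi_total)
}

# Core accrual: propagate the cohort and accumulate outcomes. All arguments
# are numeric vectors over parameter draws (length-1 for the deterministic
# case); the cycle loop is the Markov propagation itself, vectorized across
# draws. Rewards are counted at the end of cycles 1..horizon with no
# half-cycle correction; the treatment cost falls at cycle 0 undiscounted;
# the adverse-event QALY loss falls at cycle 1 with effect discounting.
.accrue <- function(os, pfs, u_stable, u_progression, ae_disutility,
                    treatment_cost, cost_stable, cost_progression, settings) {
  h <- settings$horizon
  ve <- 1 / (1 + settings$discount_effects)
  vc <- 1 / (1 + settings$discount_costs)
  stable <- rep_len(1, length(os))
  prog <- rep_len(0, length(os))
  ly <- qaly <- state_cost <- 0
  for (t in seq_len(h)) {
    prog <- prog * os + stable * (os - pfs)
    stable <- stable * pfs
    ly <- ly + stable + prog
    qaly <- qaly + (u_stable * stable + u_progression * prog) * ve^t
    state_cost <- state_cost + (cost_stable * stable + cost_progression * prog) * vc^t
  }
  ae_loss <- ae_disutility * ve
  data.frame(ly = ly,
             qaly = qaly - ae_loss,
             cost = treatment_cost + state_cost,
             treatment_cost = treatment_cost,
             state_cost = state_cost,
             ae_qaly_loss = ae_loss)
}

.get <- function(draws, col) {
  if (is.null(draws[[col]])) stop("parameter column missing: ", col)
  draws[[col]]
}

# Strategy-level pieces assembled from a draw data frame (columns laid out as
# in parameter_means()).
.ipi_treatment_cost <- function(draws) {
  lik <- sapply(.ae_events$ipi, function(e) .get(draws, paste0("ipi_ae_", e)))
  cost <- sapply(.ae_events$ipi, function(e) .get(draws, paste0("ipi_cost_ae_", e)))
  if (is.null(dim(lik))) {
    ae <- sum(lik * cost)
  } else {
    ae <- rowSums(lik * cost)
  }
  .get(draws, "ipi_cost_drug") + .get(draws, "ipi_cost_administration") + ae
}

.strategy_ae_disutility <- function(draws, strategy, duration) {
  events <- .ae_events[[strategy]]
  lik <- sapply(events, function(e) .get(draws, paste0(strategy, "_ae_", e)))
  dec <- sapply(.ae_decrement_for(events), function(d) .get(draws, d))
  if (is.null(dim(lik))) sum(lik * dec) * duration else rowSums(lik * dec) * duration
}

#' Evaluate both strategies over a set of parameter values
#'
#' The workhorse evaluator: takes one or more parameter sets (rows) in the
#' layout of [parameter_means()] / [draw_parameter_sets()] and runs the
#' three-state cohort model for both strategies on each row. The ipilimumab
#' treatment cost (drug + administration + expected adverse-event management)
#' feeds the TIL composite treatment cost, so both strategies are evaluated
#' on the same draw.
#'
#' @param draws A data frame of parameter values, one row per draw.
#' @param settings A [model_settings()] object.
#' @return A data frame with one row per draw: `ly`, `qaly`, `cost` suffixed
#'   `_til` and `_ipi`, plus treatment-cost components.
#' @export
evaluate_cohort <- function(draws, settings = model_settings()) {
  dur <- settings$ae_disutility_duration
  ipi_treat <- .ipi_treatment_cost(draws)
  ipi <- .accrue(
    os = .get(draws, "ipi_os"), pfs = .get(draws, "ipi_pfs"),
    u_stable = .get(draws, "u_stable"), u_progression = .get(draws, "u_progression"),
    ae_disutility = .strategy_ae_disutility(draws, "ipi", dur),
    treatment_cost = ipi_treat,
    cost_stable = .get(draws, "cost_stable"),
    cost_progression = .get(draws, "cost_progression"),
    settings = settings
  )
  til_price <- .get(draws, "til_cost_production") + .get(draws, "til_cost_hospital")
  til_treat <- til_expected_treatment_cost(
    til_price = til_price,
    production_cost = .get(draws, "til_cost_production"),
    ipi_total = ipi_treat,
    f_lab = .get(draws, "til_f_lab"),
    f_prog = .get(draws, "til_f_progression")
  )
  til <- .accrue(
    os = .get(draws, "til_os"), pfs = .get(draws, "til_pfs"),
    u_stable = .get(draws, "u_stable"), u_progression = .get(draws, "u_progression"),
    ae_disutility = .strategy_ae_disutility(draws, "til", dur),
    treatment_cost = til_treat,
    cost_stable = .get(draws, "cost_stable"),
    cost_progression = .get(draws, "cost_progression"),
    settings = settings
  )
  out <- cbind(setNames(til, paste0(names(til), "_til")),
               setNames(ipi, paste0(names(ipi), "_ipi")))
  rownames(out) <- NULL
  out
}

#' Incremental cost-effectiveness of one strategy over a comparator
#'
#' Computes incremental cost, QALYs and life-years, classifies the result
#' (dominant: cheaper and more effective; dominated: costlier and less
#' effective), and reports the ICER only when the cost and effect differences
#' share a sign. A zero effect difference leaves the ICER undefined.
#'
#' @param new,comparator Lists (or one-row data frames) with elements `cost`,
#'   `qaly`, `ly`.
#' @param effect Which effect difference the ICER divides by: `"qaly"`
#'   (default) or `"ly"`.
#' @return A list of class `incremental_result` with `d_cost`, `d_qaly`,
#'   `d_ly`, `classification` and `icer` (`NA` unless classification is
#'   `"icer"`).
#' @export
incremental <- function(new, comparator, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  d_cost <- new$cost - comparator$cost
  d_qaly <- new$qaly - comparator$qaly
  d_ly <- new$ly - comparator$ly
  d_eff <- if (effect == "qaly") d_qaly else d_ly
  if (d_cost < 0 && d_eff > 0) {
    cls <- "dominant"; icer <- NA_real_
  } else if (d_cost > 0 && d_eff < 0) {
    cls <- "dominated"; icer <- NA_real_
  } else if (d_eff == 0) {
    cls <- "undefined"; icer <- NA_real_
  } else {
    cls <- "icer"; icer <- d_cost / d_eff
  }
  structure(list(d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
                 classification = cls, icer = icer, effect = effect),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental result (TIL vs comparator, per %s):\n", x$effect))
  cat(sprintf("  d_cost: %+.0f EUR  d_qaly: %+.3f  d_ly: %+.3f\n",
              x$d_cost, x$d_qaly, x$d_ly))
  cat("  classification:", x$classification,
      if (x$classification == "icer") sprintf("(%.0f EUR per %s)", x$icer, x$effect) else "",
      "\n")
  invisible(x)
}

#' Deterministic base-case analysis
#'
#' Evaluates both strategies at the parameter-table means and computes the
#' incremental comparison of TIL versus ipilimumab.
#'
#' @param tbl A parameter table (default [builtin_table1()]).
#' @param settings A [model_settings()] object.
#' @return A list of class `cea_base_case` with elements `til`, `ipi`
#'   (each: `ly`, `qaly`, `cost` and components) and `incremental`.
#' @examples
#' base_case()
#' @export
base_case <- function(tbl = builtin_table1(), settings = model_settings()) {
  ev <- evaluate_cohort(parameter_means(tbl), settings)
  pick <- function(arm) {
    as.list(setNames(as.numeric(ev[1, paste0(c("ly", "qaly", "cost", "treatment_cost",
                                               "state_cost", "ae_qaly_loss"), "_", arm)]),
                     c("ly", "qaly", "cost", "treatment_cost", "state_cost", "ae_qaly_loss")))
  }
  til <- pick("til"); ipi <- pick("ipi")
  structure(list(til = til, ipi = ipi,
                 incremental = incremental(til, ipi),
                 settings = settings),
            class = "cea_base_case")
}

#' @export
print.cea_base_case <- function(x, ...) {
  cat("Base case (per patient, costs discounted at",
      sprintf("%.1f%%,", 100 * x$settings$discount_costs),
      "effects at", sprintf("%.1f%%):\n", 100 * x$settings$discount_effects))
  for (arm in c("til", "ipi")) {
    o <- x[[arm]]
    cat(sprintf("  %-11s LY %.2f  QALY %.2f  cost %s EUR\n",
                if (arm == "til") "TIL:" else "ipilimumab:",
                o$ly, o$qaly, format(round(o$cost), big.mark = ",")))
  }
  print(x$incremental)
  invisible(x)
}
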