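#' Beta distribution shapes from a mean and standard error
#'
#' Method-of-moments parameterization used for every probability and utility
#' parameter in the probabilistic sensitivity analysis: the returned shapes
#' give a Beta distribution whose analytic mean and standard deviation equal
#' the requested values exactly. Requires `se^2 < mean * (1 - mean)` (the
#' Bernoulli variance bound); otherwise no Beta distribution exists.
#'
#' @param mean Mean proportion, strictly inside (0, 1). Vectorized.
#' @param se Standard error, strictly positive.
#' @return A list with numeric components `shape1` and `shape2`.
#' @examples
#' beta_params_from_moments(0.5, sqrt(1 / 12))  # uniform: shapes (1, 1)
#' beta_params_from_moments(0.175, 0.012)
#' @export
beta_params_from_moments <- function(mean, se) {
  if (any(mean <= 0) || any(mean >= 1)) stop("Beta mean must lie strictly inside (0, 1).")
  if (any(se <= 0)) stop("`se` must be strictly positive (use a fixed parameter for se = 0).")
  if (any(se^2 >= mean * (1 - mean))) {
    stop("no Beta distribution has se^2 >= mean * (1 - mean).")
  }
  k <- mean * (1 - mean) / se^2 - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Gamma distribution shape and scale from a mean and coefficient of variation
#'
#' Cost parameters are reported as a mean with a +/- 25% spread; this is
#' interpreted as a coefficient of variation of 0.25 and moment-matched to a
#' Gamma distribution: `shape = 1 / cv^2`, `scale = mean * cv^2`, so the
#' implied mean and standard deviation (`mean * cv`) match the request
#' exactly.
#'
#' @param mean Mean cost (> 0, EUR). Vectorized.
#' @param cv Coefficient of variation (> 0), default 0.25.
#' @return A list with numeric components `shape` and `scale`.
#' @examples
#' gamma_params_from_moments(62000)        # shape 16, scale 3875
#' gamma_params_from_moments(90100, 0.25)  # implied SE 22525
#' @export
gamma_params_from_moments <- function(mean, cv = 0.25) {
  if (any(mean <= 0)) stop("Gamma mean must be strictly positive.")
  if (any(cv <= 0)) stop("`cv` must be strictly positive.")
  list(shape = 1 / cv^2 + 0 * mean, scale = mean * cv^2)
}

.gamma_cv <- 0.25

.row <- function(name, strategy, group, mean, se, distribution) {
  data.frame(name = name, strategy = strategy, group = group,
             mean = mean, se = se, distribution = distribution,
             stringsAsFactors = FALSE)
}

.cost_rows <- function(strategy, names, means) {
  .row(names, strategy, "cost", means, .gamma_cv * means, "gamma")
}

#' Built-in base-case parameter table
#'
#' The complete input table of the base-case model: 1-year overall and
#' progression-free survival probabilities per strategy, health-state
#' utilities, adverse-event utility decrements and likelihoods, TIL failure
#' fractions, and all cost components in EUR. Probabilities and utilities
#' carry Beta distributions (moment-matched from mean and SE); costs carry
#' Gamma distributions with a coefficient of variation of 0.25.
#'
#' Strategy labels: `"til"`, `"ipi"`, `"shared"` (parameters common to both
#' arms: utilities, utility decrements, follow-up and progressive-disease
#' costs).
#'
#' @return A data frame with columns `name`, `strategy`, `group`, `mean`,
#'   `se`, `distribution`.
#' @examples
#' tbl <- builtin_table1()
#' # ipilimumab treatment total: drug + administration + expected AE cost
#' sum(tbl$mean[tbl$strategy == "ipi" & tbl$name %in% c("cost_drug", "cost_administration")])
#' @export
builtin_table1 <- function() {
  ae_cost <- function(ev) paste0("cost_ae_", ev)
  tbl <- rbind(
    # 1-year survival probabilities
    .row(c("pfs", "os"), "ipi", "survival", c(0.175, 0.366), c(0.012, 0.018), "beta"),
    .row(c("pfs", "os"), "til", "survival", c(0.234, 0.412), c(0.089, 0.098), "beta"),
    # health-state utilities (assumed equal across strategies)
    .row(c("u_stable", "u_progression"), "shared", "utility", c(0.850, 0.590), 0.020, "beta"),
    # adverse-event utility decrements
    .row(paste0("du_", c("fatigue", "diarrhea", "colitis", "neutropenia",
                         "dyspnea", "flu_like", "anaemia")),
         "shared", "disutility",
         c(0.090, 0.060, 0.130, 0.130, 0.100, 0.090, 0.110), 0.020, "beta"),
    # adverse-event likelihoods
    .row(paste0("ae_", .ae_events$ipi), "ipi", "ae_likelihood",
         c(0.070, 0.060, 0.060, 0.040, 0.100, 0.030), 0.015, "beta"),
    .row(paste0("ae_", .ae_events$til), "til", "ae_likelihood",
         c(0.001, 0.001, 0.560, 0.020, 0.220, 0.440),
         c(0.001, 0.001, 0.100, 0.015, 0.100, 0.100), "beta"),
    # TIL failure fractions: lab failure and progression before infusion
    .row(c("f_lab", "f_progression"), "til", "failure", 0.100, 0.015, "beta"),
    # costs (EUR): ipilimumab drug, administration, per-event AE management
    .cost_rows("ipi", c("cost_drug", "cost_administration"), c(90100, 473)),
    .cost_rows("ipi", ae_cost(.ae_events$ipi), c(198, 580, 1115, 100, 7680, 898)),
    # costs (EUR): TIL production and hospital components (price = sum)
    .cost_rows("til", c("cost_production", "cost_hospital"), c(35500, 26500)),
    # costs (EUR): annual state costs, shared
    .cost_rows("shared", c("cost_stable", "cost_progression"), c(516, 9125))
  )
  rownames(tbl) <- NULL
  tbl
}

# Parameter names required per strategy label.
.required_parameters <- function() {
  list(
    ipi = c("pfs", "os", paste0("ae_", .ae_events$ipi),
            "cost_drug", "cost_administration", paste0("cost_ae_", .ae_events$ipi)),
    til = c("pfs", "os", paste0("ae_", .ae_events$til),
            "f_lab", "f_progression", "cost_production", "cost_hospital"),
    shared = c("u_stable", "u_progression",
               paste0("du_", c("fatigue", "diarrhea", "colitis", "neutropenia",
                               "dyspnea", "flu_like", "anaemia")),
               "cost_stable", "cost_progression")
  )
}

#' Validate a model parameter table
#'
#' Checks structure (columns, required parameters present exactly once),
#' value domains (probabilities and utilities in \[0, 1\], costs non-negative),
#' distribution assignments (`beta` only for \[0, 1\] quantities, `gamma` only
#' for costs, `fixed` iff `se == 0`), Beta moment validity
#' (`se^2 < mean (1 - mean)`), and the structural constraint `pfs <= os`
#' within each strategy. Errors name the offending row.
#'
#' @param tbl A parameter table as returned by [builtin_table1()].
#' @return The table, invisibly, if valid.
#' @export
validate_parameter_table <- function(tbl) {
  cols <- c("name", "strategy", "group", "mean", "se", "distribution")
  if (!is.data.frame(tbl) || !all(cols %in% names(tbl))) {
    stop("parameter table must have columns: ", paste(cols, collapse = ", "))
  }
  req <- .required_parameters()
  bad_strat <- setdiff(unique(tbl$strategy), names(req))
  if (length(bad_strat)) stop("unknown strategy label(s): ", paste(bad_strat, collapse = ", "))
  for (s in names(req)) {
    have <- tbl$name[tbl$strategy == s]
    if (anyDuplicated(have)) {
      stop("duplicate parameter(s) for strategy '", s, "': ",
           paste(unique(have[duplicated(have)]), collapse = ", "))
    }
    missing <- setdiff(req[[s]], have)
    if (length(missing)) {
      stop("missing parameter(s) for strategy '", s, "': ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(have, req[[s]])
    if (length(extra)) {
      stop("unrecognized parameter(s) for strategy '", s, "': ",
           paste(extra, collapse = ", "))
    }
  }
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    id <- paste0(r$strategy, "/", r$name)
    if (!is.finite(r$mean) || !is.finite(r$se) || r$se < 0) {
      stop("row ", id, ": mean must be finite and se non-negative.")
    }
    is_prob <- r$group %in% c("survival", "utility", "disutility", "ae_likelihood", "failure")
    if (is_prob && (r$mean < 0 || r$mean > 1)) {
      stop("row ", id, ": ", r$group, " mean must lie in [0, 1].")
    }
    if (r$group == "cost" && r$mean < 0) stop("row ", id, ": cost mean must be non-negative.")
    if (r$se == 0 && r$distribution != "fixed") {
      stop("row ", id, ": se = 0 requires distribution 'fixed'.")
    }
    if (r$se > 0 && !r$distribution %in% c("beta", "gamma")) {
      stop("row ", id, ": distribution must be 'beta', 'gamma', or 'fixed'.")
    }
    if (r$distribution == "beta") {
      if (!is_prob) stop("row ", id, ": 'beta' is only valid for [0, 1] quantities.")
      if (r$se^2 >= r$mean * (1 - r$mean)) {
        stop("row ", id, ": no Beta distribution has se^2 >= mean*(1-mean).")
      }
    }
    if (r$distribution == "gamma" && r$group != "cost") {
      stop("row ", id, ": 'gamma' is only valid for cost parameters.")
    }
  }
  for (s in c("til", "ipi")) {
    pfs <- tbl$mean[tbl$strategy == s & tbl$name == "pfs"]
    os <- tbl$mean[tbl$strategy == s & tbl$name == "os"]
    if (pfs > os) stop("strategy '", s, "': pfs (", pfs, ") exceeds os (", os, ").")
  }
  invisible(tbl)
}

#' Read or write a parameter table as CSV
#'
#' CSV dialect: header `name,strategy,group,mean,se,distribution`, dot decimal
#' separator. The written file round-trips through `load_parameter_table()`
#' to an identical specification.
#'
#' @param path Path to a CSV file.
#' @param tbl A valid parameter table.
#' @return `load_parameter_table()` returns the validated table;
#'   `write_parameter_table()` returns `path` invisibly.
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  validate_parameter_table(tbl)
  tbl
}

#' @rdname load_parameter_table
#' @export
write_parameter_table <- function(tbl, path) {
  validate_parameter_table(tbl)
  write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model settings
#'
#' Assembles and validates the run settings of the cohort model and its
#' downstream analyses.
#'
#' @param horizon Number of annual cycles (default 10).
#' @param cohort_size Presentational cohort size; all outcomes are per
#'   patient (default 1000).
#' @param discount_costs Annual discount rate for costs (default 0.04).
#' @param discount_effects Annual discount rate for effects (default 0.015).
#' @param wtp_threshold Willingness-to-pay ceiling ratio, EUR/QALY
#'   (default 80000).
#' @param wtp_grid Evaluation grid of thresholds for acceptability curves
#'   (default 0 to 200000 by 5000; must be strictly increasing).
#' @param ae_disutility_duration Duration, in years, over which adverse-event
#'   utility decrements apply (default 0.25, i.e. three months; applied once,
#'   at cycle 1). This is the one free accrual constant of the model; 0.25 is
#'   the round value inside the narrow interval consistent with all four
#'   published QALY figures (base case and equal-discounting scenario, both
#'   strategies).
#' @param psa_iterations Monte Carlo iterations for the probabilistic
#'   analysis (default 10000).
#' @param voi_population Patients per year who would benefit from the
#'   decision (default 400).
#' @param voi_years Decision horizon, years, for population scaling of the
#'   value of information (default 10).
#' @param voi_discount Annual discount rate for the beneficial population
#'   (default 0.04, the cost rate).
#' @return A validated list of class `cea_settings`.
#' @export
model_settings <- function(horizon = 10L,
                           cohort_size = 1000L,
                           discount_costs = 0.04,
                           discount_effects = 0.015,
                           wtp_threshold = 80000,
                           wtp_grid = seq(0, 200000, by = 5000),
                           ae_disutility_duration = 0.25,
                           psa_iterations = 10000L,
                           voi_population = 400,
                           voi_years = 10,
                           voi_discount = 0.04) {
  s <- list(horizon = as.integer(horizon), cohort_size = as.integer(cohort_size),
            discount_costs = discount_costs, discount_effects = discount_effects,
            wtp_threshold = wtp_threshold, wtp_grid = as.numeric(wtp_grid),
            ae_disutility_duration = ae_disutility_duration,
            psa_iterations = as.integer(psa_iterations),
            voi_population = voi_population, voi_years = voi_years,
            voi_discount = voi_discount)
  if (s$horizon < 1L) stop("`horizon` must be at least 1 cycle.")
  if (s$discount_costs < 0 || s$discount_effects < 0) stop("discount rates must be non-negative.")
  if (s$wtp_threshold < 0) stop("`wtp_threshold` must be non-negative.")
  if (length(s$wtp_grid) < 1L || any(diff(s$wtp_grid) <= 0)) {
    stop("`wtp_grid` must be strictly increasing.")
  }
  if (s$ae_disutility_duration < 0) stop("`ae_disutility_duration` must be non-negative.")
  if (s$psa_iterations < 1L) stop("`psa_iterations` must be at least 1.")
  if (s$voi_population < 0 || s$voi_years < 0 || s$voi_discount < 0) {
    stop("value-of-information settings must be non-negative.")
  }
  structure(s, class = "cea_settings")
}

#' @rdname model_settings
#' @param path Path to a JSON settings file.
#' @export
load_settings <- function(path) {
  if (!file.exists(path)) stop("settings file not found: ", path)
  do.call(model_settings, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname model_settings
#' @param settings A `cea_settings` object.
#' @export
write_settings <- function(settings, path) {
  jsonlite::write_json(unclass(settings), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Draw-matrix column name for a table row: shared parameters are unprefixed,
# strategy-specific ones carry "til_" / "ipi_".
.param_cols <- function(tbl) {
  ifelse(tbl$strategy == "shared", tbl$name, paste(tbl$strategy, tbl$name, sep = "_"))
}

#' Deterministic parameter values from a table
#'
#' Returns the table's means as a one-row data frame in the layout consumed
#' by [evaluate_cohort()]: shared parameters keep their name, strategy
#' parameters are prefixed `til_` or `ipi_`.
#'
#' @param tbl A valid parameter table.
#' @return A one-row data frame of parameter means.
#' @export
parameter_means <- function(tbl) {
  validate_parameter_table(tbl)
  as.data.frame(as.list(setNames(tbl$mean, .param_cols(tbl))))
}
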