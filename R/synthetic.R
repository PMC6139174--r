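#' Generate synthetic single-arm trial outcomes
#'
#' Emulates the phase-II evidence base of the pooling stage: independent
#' binomial event counts at a common true rate, one per arm size. Boundary
#' draws (0 or n events), which the logit-scale pooling domain excludes, are
#' resampled; the number of resamples is recorded in the `"resampled"`
#' attribute.
#'
#' @param true_rate True event probability, strictly inside (0, 1).
#' @param arm_sizes Integer vector of arm sizes (each >= 2).
#' @param seed Optional integer seed.
#' @return A data frame with columns `study`, `events`, `n`, and attribute
#'   `resampled`.
#' @examples
#' gen_trial_outcomes(0.5, c(20, 31), seed = 1)
#' @export
gen_trial_outcomes <- function(true_rate, arm_sizes, seed = NULL) {
  if (true_rate <= 0 || true_rate >= 1) stop("`true_rate` must lie strictly inside (0, 1).")
  if (any(arm_sizes < 2)) stop("arm sizes must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  resampled <- 0L
  events <- vapply(arm_sizes, function(n) {
    x <- stats::rbinom(1L, n, true_rate)
    while (x == 0L || x == n) {
      resampled <<- resampled + 1L
      x <- stats::rbinom(1L, n, true_rate)
    }
    x
  }, integer(1))
  structure(data.frame(study = seq_along(arm_sizes),
                       events = events, n = as.integer(arm_sizes)),
            resampled = resampled)
}

#' Perturb a parameter table
#'
#' Stress-test input generator: each uncertain parameter's mean is replaced
#' by a draw from its own sampling distribution with the standard error
#' scaled by `scale` (so `scale = 0` returns the table unchanged). Survival
#' pairs violating `pfs <= os`, and any draw that would fail table
#' validation (e.g. a Beta mean too close to the boundary for its stated
#' SE), are resampled. The emitted table always passes
#' [validate_parameter_table()].
#'
#' @param tbl A valid parameter table.
#' @param scale Non-negative multiplier on each SE.
#' @param seed Optional integer seed.
#' @return A parameter table of the same shape as `tbl`.
#' @export
perturb_parameter_table <- function(tbl, scale = 1, seed = NULL) {
  validate_parameter_table(tbl)
  if (scale < 0) stop("`scale` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  if (scale == 0) return(tbl)
  out <- tbl
  draw_mean <- function(r) {
    if (r$se == 0 || r$distribution == "fixed") return(r$mean)
    if (r$distribution == "beta") {
      p <- beta_params_from_moments(r$mean, r$se * scale)
      repeat {
        x <- rbeta(1L, p$shape1, p$shape2)
        # keep the emitted row Beta-valid under its stated (unscaled) SE
        if (x > 0 && x < 1 && r$se^2 < x * (1 - x)) return(x)
      }
    } else {
      p <- gamma_params_from_moments(r$mean, cv = r$se * scale / r$mean)
      max(rgamma(1L, shape = p$shape, scale = p$scale), .Machine$double.eps)
    }
  }
  for (i in seq_len(nrow(out))) out$mean[i] <- draw_mean(tbl[i, ])
  for (s in c("til", "ipi")) {
    i_pfs <- which(out$strategy == s & out$name == "pfs")
    i_os <- which(out$strategy == s & out$name == "os")
    while (out$mean[i_pfs] > out$mean[i_os]) {
      out$mean[i_pfs] <- draw_mean(tbl[i_pfs, ])
      out$mean[i_os] <- draw_mean(tbl[i_os, ])
    }
  }
  validate_parameter_table(out)
  out
}

#' Degenerate fixtures for invariant checks
#'
#' Edge-case inputs used by the test suite and useful for model exploration:
#' \describe{
#'   \item{zero_uncertainty}{The base table with every SE set to 0 (all
#'     distributions `fixed`): a PSA over it reproduces the base case in
#'     every iteration, acceptability probabilities are 0 or 1, and the
#'     expected value of perfect information is 0.}
#'   \item{equal_strategies}{A table in which TIL is made identical to
#'     ipilimumab: same survival, same adverse-event profile, no failures,
#'     and a TIL price equal to the total ipilimumab treatment cost. All
#'     incremental outcomes are exactly 0.}
#'   \item{settings_zero_discount}{Settings with both discount rates and the
#'     adverse-event disutility duration set to 0 (closed-form QALY checks).}
#'   \item{settings_single_cycle}{Settings with a one-cycle horizon
#'     (life-years equal the 1-year survival probability).}
#' }
#'
#' @return A named list with elements `zero_uncertainty`, `equal_strategies`
#'   (parameter tables) and `settings_zero_discount`, `settings_single_cycle`
#'   (settings).
#' @export
degenerate_fixtures <- function() {
  base <- builtin_table1()

  zero <- base
  zero$se <- 0
  zero$distribution <- "fixed"

  eq <- base
  fix_at <- function(tbl, strategy, name, value) {
    i <- which(tbl$strategy == strategy & tbl$name == name)
    tbl$mean[i] <- value; tbl$se[i] <- 0; tbl$distribution[i] <- "fixed"
    tbl
  }
  copy_from_ipi <- function(tbl, name) {
    i <- which(tbl$strategy == "til" & tbl$name == name)
    j <- which(tbl$strategy == "ipi" & tbl$name == name)
    tbl$mean[i] <- tbl$mean[j]; tbl$se[i] <- tbl$se[j]
    tbl$distribution[i] <- tbl$distribution[j]
    tbl
  }
  for (nm in c("pfs", "os")) eq <- copy_from_ipi(eq, nm)
  # same adverse-event disutility profile: TIL mirrors the ipilimumab
  # likelihood for events present in both arms; events unique to one arm
  # (TIL neutropenia, ipilimumab colitis) are zeroed in both.
  for (ev in intersect(.ae_events$til, .ae_events$ipi)) {
    eq <- copy_from_ipi(eq, paste0("ae_", ev))
  }
  for (ev in setdiff(.ae_events$til, .ae_events$ipi)) {
    eq <- fix_at(eq, "til", paste0("ae_", ev), 0)
  }
  for (ev in setdiff(.ae_events$ipi, .ae_events$til)) {
    eq <- fix_at(eq, "ipi", paste0("ae_", ev), 0)
  }
  eq <- fix_at(eq, "til", "f_lab", 0)
  eq <- fix_at(eq, "til", "f_progression", 0)
  # TIL price equal to the ipilimumab treatment total (computed on the
  # modified likelihoods), so treatment costs coincide exactly
  ipi_total <- .ipi_treatment_cost(parameter_means(eq))
  eq <- fix_at(eq, "til", "cost_production", ipi_total)
  eq <- fix_at(eq, "til", "cost_hospital", 0)

  list(
    zero_uncertainty = validate_parameter_table(zero),
    equal_strategies = validate_parameter_table(eq),
    settings_zero_discount = model_settings(discount_costs = 0,
                                            discount_effects = 0,
                                            ae_disutility_duration = 0),
    settings_single_cycle = model_settings(horizon = 1L)
  )
}
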