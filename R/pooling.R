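#' Logit and inverse-logit transforms
#'
#' Thin wrappers around [stats::qlogis()] and [stats::plogis()] with strict
#' domain checks, used throughout the evidence-pooling step. Proportions must
#' lie strictly inside (0, 1): at the boundary the logit (and the logit-scale
#' sampling variance of a proportion) is undefined.
#'
#' @param p Proportion(s) strictly inside (0, 1).
#' @param x Real number(s).
#' @return `logit()` returns log-odds; `inv_logit()` returns proportions.
#' @examples
#' logit(0.35)
#' inv_logit(logit(0.35))
#' @export
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1); the logit is undefined at the boundary.")
  }
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  if (!is.numeric(x) || any(is.na(x))) stop("`x` must be numeric and non-missing.")
  plogis(x)
}

.check_trial_outcome <- function(events, n) {
  if (length(events) != length(n)) stop("`events` and `n` must have equal length.")
  if (length(events) == 0L) stop("at least one trial outcome is required.")
  if (any(events != round(events)) || any(n != round(n))) {
    stop("`events` and `n` must be whole numbers.")
  }
  if (any(n < 2)) stop("arm size `n` must be at least 2.")
  if (any(events <= 0) || any(events >= n)) {
    stop("boundary counts (0 or n events) are rejected: the logit-scale ",
         "variance 1/events + 1/(n - events) is undefined there.")
  }
  invisible(TRUE)
}

.pooled_proportion <- function(logit_mean, logit_se, level, k) {
  z <- qnorm(1 - (1 - level) / 2)
  structure(
    list(
      mean = inv_logit(logit_mean),
      ci_low = inv_logit(logit_mean - z * logit_se),
      ci_high = inv_logit(logit_mean + z * logit_se),
      logit_mean = logit_mean,
      logit_se = logit_se,
      level = level,
      k = k
    ),
    class = "pooled_proportion"
  )
}

#' Logit-scale confidence interval for a single proportion
#'
#' Computes the binomial proportion `events / n` with a Wald interval on the
#' log-odds scale, back-transformed to the proportion scale. The logit-scale
#' standard error is `sqrt(1/events + 1/(n - events))`; the normal quantile is
#' used (not the t).
#'
#' @param events Number of patients with the outcome (0 < events < n).
#' @param n Arm size (>= 2).
#' @param level Two-sided confidence level, default 0.95.
#' @return A `pooled_proportion` object: a list with `mean`, `ci_low`,
#'   `ci_high`, `logit_mean`, `logit_se`, `level`, and `k` (number of studies).
#' @examples
#' proportion_logit_ci(7, 20)   # 0.350 (0.177-0.574)
#' proportion_logit_ci(20, 31)  # 0.645 (0.466-0.791)
#' @seealso [pool_fixed()]
#' @export
proportion_logit_ci <- function(events, n, level = 0.95) {
  if (length(events) != 1L || length(n) != 1L) {
    stop("`proportion_logit_ci()` takes a single arm; use `pool_fixed()` for several.")
  }
  .check_level(level)
  .check_trial_outcome(events, n)
  .pooled_proportion(
    logit_mean = logit(events / n),
    logit_se = sqrt(1 / events + 1 / (n - events)),
    level = level, k = 1L
  )
}

#' Fixed-effect inverse-variance pooling of proportions on the logit scale
#'
#' Pools single-arm binomial proportions by weighting each study's log-odds by
#' the inverse of its sampling variance `1/events + 1/(n - events)`. The
#' pooled log-odds and its standard error `sqrt(1 / sum(weights))` are
#' back-transformed to the proportion scale. One study pools to exactly its
#' own `proportion_logit_ci()`.
#'
#' @param events Integer vector of event counts, one per study arm.
#' @param n Integer vector of arm sizes.
#' @inheritParams proportion_logit_ci
#' @return A `pooled_proportion` object (see [proportion_logit_ci()]).
#' @examples
#' pool_fixed(c(7, 20), c(20, 31))  # 1-year OS: 0.531 (0.389-0.667)
#' pool_fixed(c(3, 10), c(20, 31))  # 1-year PFS: 0.266 (0.160-0.408)
#' @export
pool_fixed <- function(events, n, level = 0.95) {
  .check_level(level)
  .check_trial_outcome(events, n)
  yi <- logit(events / n)
  vi <- 1 / events + 1 / (n - events)
  wi <- 1 / vi
  .pooled_proportion(
    logit_mean = sum(wi * yi) / sum(wi),
    logit_se = sqrt(1 / sum(wi)),
    level = level, k = length(events)
  )
}

.check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single confidence level in (0, 1).")
  }
  invisible(TRUE)
}

#' @export
print.pooled_proportion <- function(x, ...) {
  cat(sprintf(
    "Pooled proportion (fixed effect, logit scale, %d %s)\n  %.3f (%.0f%% CI %.3f-%.3f)\n",
    x$k, if (x$k == 1L) "study" else "studies",
    x$mean, 100 * x$level, x$ci_low, x$ci_high
  ))
  invisible(x)
}
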