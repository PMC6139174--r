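#' Sample parameter sets for the probabilistic analysis
#'
#' Draws `n` independent parameter sets from the table's distributions: Beta
#' (moment-matched from mean and SE) for probabilities and utilities, Gamma
#' (moment-matched, CV = se/mean) for costs; `fixed` rows pass through their
#' mean. OS and PFS are sampled independently within each strategy; draws
#' violating `pfs <= os` are rejected and the (os, pfs) pair redrawn jointly,
#' with the number of rejections recorded in the `"rejections"` attribute.
#'
#' @param tbl A valid parameter table.
#' @param n Number of draws.
#' @return A data frame of `n` rows in the layout of [parameter_means()],
#'   with attribute `rejections` (named count per strategy).
#' @export
draw_parameter_sets <- function(tbl, n) {
  validate_parameter_table(tbl)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1.")
  cols <- .param_cols(tbl)
  draw_row <- function(r, how_many) {
    if (r$se == 0 || r$distribution == "fixed") {
      rep_len(r$mean, how_many)
    } else if (r$distribution == "beta") {
      p <- beta_params_from_moments(r$mean, r$se)
      rbeta(how_many, p$shape1, p$shape2)
    } else {
      p <- gamma_params_from_moments(r$mean, cv = r$se / r$mean)
      rgamma(how_many, shape = p$shape, scale = p$scale)
    }
  }
  draws <- as.data.frame(lapply(seq_len(nrow(tbl)), function(i) draw_row(tbl[i, ], n)))
  names(draws) <- cols
  rejections <- c(til = 0L, ipi = 0L)
  for (s in c("til", "ipi")) {
    os_col <- paste0(s, "_os"); pfs_col <- paste0(s, "_pfs")
    os_row <- tbl[tbl$strategy == s & tbl$name == "os", ]
    pfs_row <- tbl[tbl$strategy == s & tbl$name == "pfs", ]
    bad <- which(draws[[pfs_col]] > draws[[os_col]])
    while (length(bad)) {
      rejections[s] <- rejections[s] + length(bad)
      draws[[os_col]][bad] <- draw_row(os_row, length(bad))
      draws[[pfs_col]][bad] <- draw_row(pfs_row, length(bad))
      bad <- bad[draws[[pfs_col]][bad] > draws[[os_col]][bad]]
    }
  }
  attr(draws, "rejections") <- rejections
  draws
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration draws one
#' joint parameter set and evaluates both strategies on it (paired draws;
#' shared parameters such as utilities, state costs, and the ipilimumab
#' treatment cost entering the TIL failure pathway are common to both arms).
#'
#' @param tbl A parameter table (default [builtin_table1()]).
#' @param settings A [model_settings()] object.
#' @param iterations Number of iterations (default `settings$psa_iterations`).
#' @param seed Optional integer seed; when given, results are bit-reproducible.
#' @return An object of class `psa_results`: list with `samples` (data frame
#'   of per-iteration `cost`, `qaly`, `ly` per arm), `iterations`, `seed`,
#'   and `rejections`.
#' @examples
#' psa <- run_psa(iterations = 200, seed = 1)
#' quadrant_shares(psa)
#' @export
run_psa <- function(tbl = builtin_table1(), settings = model_settings(),
                    iterations = settings$psa_iterations, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_parameter_sets(tbl, iterations)
  samples <- evaluate_cohort(draws, settings)
  structure(list(samples = samples,
                 iterations = as.integer(iterations),
                 seed = seed,
                 rejections = attr(draws, "rejections")),
            class = "psa_results")
}

#' @export
print.psa_results <- function(x, ...) {
  q <- quadrant_shares(x)
  cat(sprintf("PSA: %d iterations%s; pfs<=os rejections til/ipi: %d/%d\n",
              x$iterations,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed),
              x$rejections[["til"]], x$rejections[["ipi"]]))
  cat(sprintf("  mean TIL:        QALY %.3f, cost %s EUR\n", mean(x$samples$qaly_til),
              format(round(mean(x$samples$cost_til)), big.mark = ",")))
  cat(sprintf("  mean ipilimumab: QALY %.3f, cost %s EUR\n", mean(x$samples$qaly_ipi),
              format(round(mean(x$samples$cost_ipi)), big.mark = ",")))
  cat(sprintf("  CE-plane shares (TIL vs ipi): NE %.1f%%, SE %.1f%%, SW %.1f%%, NW %.1f%%\n",
              100 * q[["NE"]], 100 * q[["SE"]], 100 * q[["SW"]], 100 * q[["NW"]]))
  invisible(x)
}

#' Net monetary benefit
#'
#' `nmb = wtp * qaly - cost`, in EUR, at willingness-to-pay `wtp` (EUR/QALY).
#'
#' @param qaly QALYs. Vectorized.
#' @param cost Cost in EUR.
#' @param wtp Willingness-to-pay threshold (>= 0).
#' @return Net monetary benefit in EUR.
#' @export
nmb <- function(qaly, cost, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative.")
  wtp * qaly - cost
}

.d_nmb <- function(psa, wtp) {
  s <- psa$samples
  nmb(s$qaly_til, s$cost_til, wtp) - nmb(s$qaly_ipi, s$cost_ipi, wtp)
}

.check_psa <- function(psa) {
  if (!inherits(psa, "psa_results") || nrow(psa$samples) == 0L) {
    stop("`psa` must be a non-empty `psa_results` object.")
  }
  invisible(TRUE)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that TIL has the
#' higher net monetary benefit. Ties (exactly equal NMB) count for the
#' comparator, which is conservative for the new technology.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Strictly increasing thresholds (EUR/QALY); default
#'   0 to 200000 by 5000.
#' @return A data frame with columns `wtp`, `prob_til`, `prob_ipi`.
#' @export
ceac <- function(psa, wtp_grid = model_settings()$wtp_grid) {
  .check_psa(psa)
  if (any(wtp_grid < 0) || any(diff(wtp_grid) <= 0)) {
    stop("`wtp_grid` must be non-negative and strictly increasing.")
  }
  p <- vapply(wtp_grid, function(l) mean(.d_nmb(psa, l) > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_til = p, prob_ipi = 1 - p)
}

#' Quadrant shares of the incremental cost-effectiveness plane
#'
#' Classifies each PSA iteration by the signs of the incremental QALYs
#' (east: TIL more effective) and incremental cost (north: TIL more costly)
#' of TIL versus ipilimumab. Boundary points go to the south-east quadrant
#' when `d_cost <= 0` and `d_qaly >= 0`; remaining boundary ties are resolved
#' clockwise (SW before NW before NE).
#'
#' @param psa A [run_psa()] result.
#' @return Named numeric vector of shares (`NE`, `SE`, `SW`, `NW`) summing
#'   to 1.
#' @export
quadrant_shares <- function(psa) {
  .check_psa(psa)
  s <- psa$samples
  dq <- s$qaly_til - s$qaly_ipi
  dc <- s$cost_til - s$cost_ipi
  se <- dq >= 0 & dc <= 0
  sw <- !se & dq < 0 & dc <= 0
  nw <- !se & !sw & dq < 0
  ne <- !(se | sw | nw)
  shares <- c(NE = mean(ne), SE = mean(se), SW = mean(sw), NW = mean(nw))
  stopifnot(abs(sum(shares) - 1) < 1e-12)
  shares
}
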