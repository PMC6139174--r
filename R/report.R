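#' Run the full analysis end to end
#'
#' Orchestrates every stage on one parameter table and settings object and
#' writes the report bundle to `out_dir`:
#' \itemize{
#'   \item `base_case.json` — per-strategy LY/QALY/cost, incremental result
#'     and dominance classification;
#'   \item `trace_til.csv`, `trace_ipi.csv` — cohort traces;
#'   \item `psa_samples.csv` — per-iteration paired costs and QALYs;
#'   \item `ceac.csv` — acceptability curve over the threshold grid;
#'   \item `quadrants.json` — CE-plane quadrant shares;
#'   \item `evpi.json` — per-person and population EVPI;
#'   \item `tornado.csv` — one-way sensitivity results;
#'   \item `run_log.json` — seed, iteration count, settings and package
#'     version, enough to reproduce the bundle.
#' }
#' Numbers are serialized at full precision; rounding is left to
#' presentation.
#'
#' @param out_dir Output directory (created if absent).
#' @param tbl A parameter table (default [builtin_table1()]).
#' @param settings A [model_settings()] object.
#' @param seed Integer seed for the probabilistic stage.
#' @return Invisibly, a list with the in-memory results (`base_case`, `psa`,
#'   `ceac`, `quadrants`, `evpi`, `tornado`).
#' @export
run_full_analysis <- function(out_dir, tbl = builtin_table1(),
                              settings = model_settings(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  validate_parameter_table(tbl)
  means <- parameter_means(tbl)

  bc <- base_case(tbl, settings)
  jsonlite::write_json(
    list(til = bc$til, ipi = bc$ipi,
         incremental = unclass(bc$incremental)),
    file.path(out_dir, "base_case.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (arm in c("til", "ipi")) {
    p <- build_transition_matrix(means[[paste0(arm, "_os")]],
                                 means[[paste0(arm, "_pfs")]])
    write.csv(run_trace(p, settings$horizon),
              file.path(out_dir, sprintf("trace_%s.csv", arm)), row.names = FALSE)
  }

  psa <- run_psa(tbl, settings, seed = seed)
  write.csv(cbind(iteration = seq_len(psa$iterations),
                  psa$samples[, c("cost_til", "qaly_til", "cost_ipi", "qaly_ipi")]),
            file.path(out_dir, "psa_samples.csv"), row.names = FALSE)

  cc <- ceac(psa, settings$wtp_grid)
  write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)

  qs <- quadrant_shares(psa)
  jsonlite::write_json(as.list(qs), file.path(out_dir, "quadrants.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ev <- evpi(psa, settings)
  jsonlite::write_json(unclass(ev), file.path(out_dir, "evpi.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  tor <- one_way_sa(tbl, settings)
  write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(seed = seed, iterations = psa$iterations,
         rejections = as.list(psa$rejections),
         settings = unclass(settings),
         package_version = as.character(packageVersion("tilcea"))),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(base_case = bc, psa = psa, ceac = cc, quadrants = qs,
                 evpi = ev, tornado = tor))
}
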