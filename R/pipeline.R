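.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
      class = c(paste0("remdkin_", name, "_error"), "remdkin_stage_error")))
  })
}

#' Run the full REMD kinetic-analysis pipeline
#'
#' Generate (or accept) a synthetic REMD run, compute the convergence
#' diagnostics (exchange acceptance, equal occupancy, energy-distribution
#' Gaussianity), detect conformational cores on the pooled d_ee
#' distribution, assign states by TBA on the continuous replica
#' trajectories, and estimate the kinetic network by direct transition
#' counting cumulated over all replicas.
#'
#' A failed energy check aborts the pipeline (condition class
#' `remdkin_energy_check_error`) unless `force = TRUE` — an uncorrected
#' field run should be re-initialised via [corrected_restart()] rather than
#' analysed.
#'
#' @param scenario A `remd_scenario`, a packaged scenario name, or an
#'   existing `remd_run`.
#' @param n_frames Frames per replica; default the scenario's nominal
#'   production length.
#' @param seed Root seed for the run.
#' @param lag Lag (ps) for the empirical propagator stored in the report.
#' @param blocks Blocks for the rate error analysis.
#' @param bin_width,prominence,core_fraction Core-detection parameters
#'   (see [detect_cores()]).
#' @param occupancy_threshold Equal-occupancy pass threshold (default
#'   `0.5 / M`).
#' @param energy_by `"temperature"` or `"replica"` for the artifact check.
#' @param force Continue past failed diagnostics.
#' @param outdir Optional directory; when given, writes
#'   `diagnostics.json`, `network.json`, `rates.txt`, `histogram.csv` and
#'   per-replica state trajectories.
#' @return A list of class `"remd_report"`: `scenario`, `run`,
#'   `diagnostics`, `cores`, `fit` (a [dtc()] object), `network`,
#'   `histogram`, `seed`.
#' @export
run_remd_pipeline <- function(scenario, n_frames = NULL, seed = 1,
                              lag = 1, blocks = 5, bin_width = 0.1,
                              prominence = 0.05, core_fraction = 0.6,
                              occupancy_threshold = NULL,
                              energy_by = "temperature",
                              force = FALSE, outdir = NULL) {
  if (inherits(scenario, "remd_run")) {
    run <- scenario
    scenario <- run$scenario
  } else {
    if (is.character(scenario)) scenario <- build_scenario(scenario)
    if (is.null(n_frames))
      n_frames <- round(scenario$production_ns * 1000 /
                          scenario$frame_interval)
    run <- .stage("simulate", simulate_remd(scenario, n_frames, seed))
  }
  diag <- .stage("diagnostics", {
    acc <- if (nrow(run$exchange)) acceptance_rate(run$exchange) else NULL
    occ <- occupancy(run, threshold = occupancy_threshold)
    en <- energy_artifact_report(run, by = energy_by)
    list(acceptance = acc, occupancy = occ, energy = en)
  })
  if (!diag$energy$pass && !force)
    stop(errorCondition(
      paste0("pipeline stage 'energy_check' failed: non-Gaussian energy ",
             "distribution(s) flagged (", diag$energy$by, " ",
             paste(diag$energy$flagged, collapse = ", "),
             "); correct the initial conditions (corrected_restart) or ",
             "rerun with force = TRUE"),
      class = c("remdkin_energy_check_error", "remdkin_stage_error")))
  dee_all <- unlist(lapply(run$replicas, function(d) d$dee))
  cores <- .stage("core_detection",
                  detect_cores(dee_all, bin_width = bin_width,
                               prominence = prominence,
                               core_fraction = core_fraction))
  assignments <- .stage("assignment",
                        lapply(run$replicas, function(d)
                          assign_tba(d$dee, cores)))
  fit <- .stage("kinetics",
                dtc(assignments, dt = scenario$frame_interval,
                    n_states = nrow(cores), blocks = blocks))
  net <- .stage("kinetics", kinetic_network_report(fit))
  h <- obs_histogram(dee_all, bin_width = bin_width)
  report <- structure(list(scenario = summary(scenario), run = run,
                           diagnostics = diag, cores = cores, fit = fit,
                           network = net, histogram = h, seed = seed,
                           n_frames = run$n_frames),
                      class = "remd_report")
  if (!is.null(outdir)) .write_report(report, outdir)
  report
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dg <- report$diagnostics
  diag_json <- list(
    schema_version = "1.0",
    seed = report$seed,
    scenario = report$scenario$name,
    n_frames = report$n_frames,
    acceptance = if (!is.null(dg$acceptance)) dg$acceptance$overall else NULL,
    occupancy_deviation = dg$occupancy$deviation,
    occupancy_pass = dg$occupancy$pass,
    energy_flagged = as.integer(dg$energy$flagged),
    energy_pass = dg$energy$pass)
  jsonlite::write_json(diag_json, file.path(outdir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  net_json <- list(schema_version = "1.0", seed = report$seed,
                   nodes = report$network$nodes,
                   edges = report$network$edges)
  jsonlite::write_json(net_json, file.path(outdir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  ed <- report$network$edges
  writeLines(c("# from to rate_per_ps se",
               sprintf("%d %d %.10g %.6g", ed$from, ed$to, ed$rate, ed$se)),
             file.path(outdir, "rates.txt"))
  utils::write.csv(data.frame(mid = report$histogram$mids,
                              density = report$histogram$density),
                   file.path(outdir, "histogram.csv"), row.names = FALSE)
  for (r in seq_along(report$run$replicas))
    write_trajectory(report$run$replicas[[r]],
                     file.path(outdir, sprintf("replica_%02d.txt", r)))
  write_exchange_log(report$run$exchange,
                     file.path(outdir, "exchange_log.txt"))
  invisible(outdir)
}

#' @export
print.remd_report <- function(x, ...) {
  cat(sprintf("REMD analysis report: scenario '%s', seed %d, %d frames/replica\n",
              x$scenario$name, x$seed, x$n_frames))
  if (!is.null(x$diagnostics$acceptance))
    cat(sprintf("  exchange acceptance: %.1f%%\n",
                100 * x$diagnostics$acceptance$overall))
  cat(sprintf("  equal occupancy: %s (deviation %.4f)\n",
              if (x$diagnostics$occupancy$pass) "pass" else "FAIL",
              x$diagnostics$occupancy$deviation))
  cat(sprintf("  energy check: %s\n",
              if (x$diagnostics$energy$pass) "pass" else "FAIL"))
  cat(sprintf("  %d state(s); populations: %s\n", nrow(x$network$nodes),
              paste(sprintf("%.1f%%", x$network$nodes$population_pct),
                    collapse = ", ")))
  cat(sprintf("  d_ee histogram mode: %.2f A\n", x$histogram$mode))
  invisible(x)
}

#' Write small packaged example datasets
#'
#' Deterministically regenerates the tiny trajectories and exchange log
#' used in examples and tests: a 200-frame, 12-replica zero-field run.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  run <- simulate_remd(build_scenario("zero_field"), n_frames = 200,
                       seed = seed)
  files <- character(0)
  for (r in seq_along(run$replicas)) {
    f <- file.path(dir, sprintf("replica_%02d.txt", r))
    write_trajectory(run$replicas[[r]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "exchange_log.txt")
  write_exchange_log(run$exchange, f)
  invisible(c(files, f))
}
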