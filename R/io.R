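# Scenario runner and fixture generator. run_scenario() is the function the
# command-line wrapper (inst/cli/eetsim.R) calls: it validates, calibrates,
# simulates, and writes the comparison tables, calibration report, a sample
# of the per-woman event log, and a reproducibility manifest.

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_scenario_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full scenario and write its artifacts
#'
#' @param config_path Optional YAML configuration path (defaults bundled).
#' @param overrides Named list of dotted-path overrides (see
#'   [load_scenario_config()]).
#' @param output_dir Directory to write into (created if needed).
#' @param seed,n Optional master-seed / cohort-size overrides.
#' @param config An already-loaded `eet_config` (alternative to
#'   `config_path`).
#' @return Invisibly, a list with the comparison, calibration and manifest.
#' @export
run_scenario <- function(config_path = NULL, overrides = list(),
                         output_dir, seed = NULL, n = NULL, config = NULL) {
  if (is.null(config)) {
    config <- load_scenario_config(config_path, overrides)
  } else if (length(overrides) > 0) {
    for (nm in names(overrides))
      config <- set_config_value(config, nm, overrides[[nm]])
  }
  if (!is.null(seed)) config$master_seed <- as.integer(seed)
  if (!is.null(n)) config$n_women <- as.numeric(n)
  report <- validate_parameters(config)
  if (nrow(report) > 0) {
    print(report)
    stop("configuration failed validation (", nrow(report), " violation(s))")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- Sys.time()
  calib <- calibrate_model(config)
  cmp <- compare_durations(config, calib = calib)

  s <- cmp$summary
  write.csv(format(s, digits = 15, scientific = FALSE, trim = TRUE),
            file.path(output_dir, "comparison_full_precision.csv"),
            row.names = FALSE)
  rounded <- s
  num <- c("mean_5y", "mean_10y", "diff", "se_diff", "se_unpaired")
  rounded[num] <- lapply(rounded[num], round, digits = 2)
  write.csv(rounded, file.path(output_dir, "comparison_table.csv"),
            row.names = FALSE)
  calibration_report(calib, file.path(output_dir, "calibration_report.csv"))

  # event-log sample: first 1000 women, both arms
  ncap <- min(1000, config$n_women)
  prof <- sample_cohort(config, n = ncap, seed = config$master_seed,
                        stream_tag = "#1")
  sim <- simulate_pair_chunk(prof, calib, config, config$master_seed,
                             stream_tag = "#1")
  ev <- rbind(
    cbind(arm = "five_year", as.data.frame(sim$five$ae)),
    cbind(arm = "ten_year", as.data.frame(sim$ten$ae)))
  write.csv(ev[, c("id", "arm", "event", "onset", "start", "end", "mult")],
            file.path(output_dir, "event_log_sample.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("eetsim")),
    config_md5 = config_digest(config),
    master_seed = config$master_seed,
    n_women = config$n_women,
    horizon = config$horizon,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = c("comparison_table.csv", "comparison_full_precision.csv",
                "calibration_report.csv", "event_log_sample.csv",
                "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(comparison = cmp, calib = calib, manifest = manifest,
                 config = config))
}

#' Generate the small bundled fixtures used by regression tests
#'
#' Writes a 1,000-woman cohort CSV and a snapshot of the aggregated
#' comparison on that cohort (at a reduced calibration sample size).
#' Regeneration with the same seed is byte-idempotent.
#'
#' @param dir Output directory.
#' @param seed Master seed for the fixture cohort.
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir, seed = 20210416) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- default_config()
  config$master_seed <- as.integer(seed)
  config$n_women <- 1000
  config$calibration$n_sim <- 50000

  prof <- sample_cohort(config, n = 1000, seed = config$master_seed,
                        stream_tag = "#1")
  cohort_path <- file.path(dir, "fixture_cohort_1000.csv")
  write.csv(format(prof, digits = 15, scientific = FALSE, trim = TRUE),
            cohort_path, row.names = FALSE)

  calib <- calibrate_model(config)
  cmp <- compare_durations(config, calib = calib)
  snap <- cmp$summary
  snap_path <- file.path(dir, "fixture_summary_1000.csv")
  write.csv(format(snap, digits = 15, scientific = FALSE, trim = TRUE),
            snap_path, row.names = FALSE)
  invisible(c(cohort_path, snap_path))
}
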