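# End-to-end orchestration: simulate | process | calibrate, with manifests
# for seeded reproducibility.

write_scan_table <- function(scans, path) {
  out <- data.frame(
    source = scans$source_id, scan = scans$scan, time = scans$time.min,
    isotopolog = scans$isotopolog,
    intensity = sprintf("%.8g", scans$intensity),
    peakNoise = sprintf("%.8g", scans$peakNoise),
    resolution = scans$resolution, microscans = scans$microscans,
    charge = scans$charge, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

manifest_new <- function(stage, seed = NULL, config = NULL, inputs = character(0)) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  list(stage = stage,
       package_version = as.character(utils::packageVersion("fragiso")),
       seed = seed, config = config, input_digests = digests,
       row_counts = list(), outputs = character(0))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Simulate a run and write its scan table plus ground-truth sidecar
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; all randomness derives from it.
#' @param mode `"sequence"` (bracketed, default) or `"single"`.
#' @param run_cfg A [run_config()] (sequence timing).
#' @param n_blocks Blocks for the bracketed sequence.
#' @param sample_deltas,reference_deltas True deltas (per mil) keyed
#'   `"fragment.element"`.
#' @param duration_min Duration for `mode = "single"`.
#' @return Invisibly, a list with paths `scan_table`, `truth`, `manifest`.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir, seed = 1L,
                         mode = c("sequence", "single"),
                         run_cfg = run_config(), n_blocks = 9L,
                         sample_deltas = numeric(0),
                         reference_deltas = numeric(0),
                         duration_min = 15) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (mode == "sequence") {
    simulate_bracketed_sequence(sample_deltas, reference_deltas, config,
                                run_cfg, n_blocks, seed = seed)
  } else {
    cfg <- config; cfg$true_deltas <- sample_deltas
    simulate_scan_table(cfg, duration_min = duration_min, seed = seed)
  }
  scan_path <- file.path(out_dir, "scan_table.tsv")
  truth_path <- file.path(out_dir, "truth.json")
  write_scan_table(sim$scans, scan_path)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE,
                       null = "null")
  man <- manifest_new("simulate", seed = seed,
                      config = unclass(config))
  man$row_counts$scans <- nrow(sim$scans)
  man$outputs <- c(scan_table = scan_path, truth = truth_path)
  man_path <- file.path(out_dir, "manifest_simulate.json")
  write_manifest(man, man_path)
  invisible(list(scan_table = scan_path, truth = truth_path,
                 manifest = man_path))
}

#' Process a scan table into delta shifts with confidence intervals
#'
#' Runs the scan-level chain (ion counts, window ratios, bracketing,
#' error propagation, CI aggregation) and writes a results table and a
#' manifest. If a standards table is supplied, calibrated results are
#' written as well (two-point or regression per fragment/element).
#'
#' @param scan_table Path to a scan table.
#' @param config A [run_config()] or path to a JSON config.
#' @param out_dir Output directory.
#' @param standards Optional standards table (data.frame or path,
#'   [read_standards_table()] schema); requires `standard_results`.
#' @param standard_results Optional measured standard results (see
#'   [cmd_calibrate()]); with `standards`, calibrated results are written
#'   too.
#' @param blocks Optional explicit block table (direct infusion).
#' @param catalog Isotopologue catalog.
#' @return Invisibly, a list with `results` (data.frame), `calibrated`
#'   (data.frame or NULL), file `paths`, and the `manifest`.
#' @export
cmd_process <- function(scan_table, config = run_config(), out_dir,
                        standards = NULL, standard_results = NULL,
                        blocks = NULL, catalog = smx_catalog()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scans <- read_scan_table(scan_table, catalog)
  results <- process_sequence(scans, config, catalog, blocks)
  res_path <- file.path(out_dir, "results.tsv")
  write_results_table(results, res_path)
  man <- manifest_new("process", config = unclass(config),
                      inputs = scan_table)
  man$row_counts$scans <- nrow(scans)
  man$row_counts$rejected <- attr(scans, "rows_rejected")
  man$row_counts$results <- nrow(results)
  man$outputs <- c(results = res_path)

  calibrated <- NULL
  if (!is.null(standards)) {
    if (is.null(standard_results))
      stop("calibration in cmd_process needs measured standard_results ",
           "alongside the standards table")
    cal <- cmd_calibrate(standard_results, standards,
                         sample_results = results, out_dir = out_dir)
    calibrated <- cal$calibrated
    man$outputs <- c(man$outputs,
                     calibrated = file.path(out_dir,
                                            "calibrated_results.tsv"))
  }
  man_path <- file.path(out_dir, "manifest_process.json")
  write_manifest(man, man_path)
  invisible(list(results = results, calibrated = calibrated,
                 paths = c(results = res_path, manifest = man_path),
                 manifest = man))
}

#' Calibrate measured standard results and apply the models to samples
#'
#' Builds one calibration model per (fragment, element) from the measured
#' standard results and the standards table (two-point when exactly two
#' standards are available, OLS regression otherwise), then inverse-maps
#' the sample results through the models.
#'
#' @param standard_results Data.frame of measured standards: columns
#'   `standard_id`, `fragment`, `element`, `delta.permil`, optionally
#'   `sigma.permil`.
#' @param standards Standards data.frame or path
#'   ([read_standards_table()]).
#' @param sample_results Results data.frame ([process_sequence()] schema)
#'   to calibrate; may be `NULL` to only fit models.
#' @param out_dir Optional output directory for the calibration report and
#'   calibrated results.
#' @param molecule A [molecule_def()].
#' @return Invisibly, list with `models`, `report` (data.frame of
#'   slope/intercept/SE per model) and `calibrated` (data.frame or NULL).
#' @export
cmd_calibrate <- function(standard_results, standards, sample_results = NULL,
                          out_dir = NULL, molecule = smx_molecule()) {
  if (is.character(standards)) standards <- read_standards_table(standards)
  models <- build_calibrations(standard_results, standards, molecule)
  report <- do.call(rbind, lapply(models, function(m) data.frame(
    fragment = m$fragment, element = m$element, kind = m$kind,
    slope = m$slope, intercept = m$intercept, slope_se = m$slope_se,
    intercept_se = m$intercept_se, n_points = m$n_points,
    stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  calibrated <- NULL
  if (!is.null(sample_results)) {
    calibrated <- sample_results
    calibrated$delta.calibrated <- NA_real_
    calibrated$sigma.calibrated <- NA_real_
    for (i in seq_len(nrow(calibrated))) {
      key <- paste(calibrated$fragment[i], calibrated$element[i], sep = ".")
      if (!key %in% names(models))
        stop("no calibration model for ", key)
      cal <- apply_calibration(models[[key]], calibrated$delta.permil[i],
                               calibrated$sigma.permil[i])
      calibrated$delta.calibrated[i] <- cal$delta
      calibrated$sigma.calibrated[i] <- cal$sigma
      calibrated$ci95.calibrated[i] <-
        calibrated$ci95.permil[i] / abs(models[[key]]$slope)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "calibration_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(calibrated))
      utils::write.table(calibrated,
                         file.path(out_dir, "calibrated_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(models = models, report = report, calibrated = calibrated))
}
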