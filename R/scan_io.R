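# Reading/writing scan-level isotopologue tables, run configurations,
# standards tables and results tables.

#' Run configuration
#'
#' Assembles the processing configuration with the method's defaults: a
#' 15-min data window, 18-min measurement blocks with the first 3 min after
#' valve switching discarded, the signal-to-noise constants C_N = 3 and
#' R_N = 240,000, and a two-sided 0.05 level for confidence intervals.
#'
#' @param mode `"direct_infusion"` or `"lc_blocks"`.
#' @param data_window_min Data window length for direct infusion (min).
#' @param switch_discard_min Discarded head of each block (min).
#' @param block_duration_min Block duration in lc_blocks mode (min).
#' @param agc_target AGC target (ions per fill); one of the method's
#'   1.0e6 / 1.5e6 / 3.0e6 settings, default 3.0e6.
#' @param c_n,r_n Ion-count constants of [ions_per_scan()].
#' @param t_alpha Two-sided significance level for CIs.
#' @param sem_method Ratio SEM estimator, `"scan"` or `"bootstrap"`.
#' @param ci_method `"rms_t"` (the method's RMS x t rule, [ci95()]) or
#'   `"replicate_sd"` ([ci95_replicate_sd()]).
#' @param pathway_tag Processing-pathway tag (e.g. `"lc_blocks/column"`)
#'   used by [identical_treatment_check()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("lc_blocks", "direct_infusion"),
                       data_window_min = 15, switch_discard_min = 3,
                       block_duration_min = 18, agc_target = 3e6,
                       c_n = 3, r_n = 240000, t_alpha = 0.05,
                       sem_method = c("scan", "bootstrap"),
                       ci_method = c("rms_t", "replicate_sd"),
                       pathway_tag = NULL) {
  mode <- match.arg(mode)
  stopifnot(data_window_min > 0, switch_discard_min > 0,
            block_duration_min > 0,
            switch_discard_min < block_duration_min,
            agc_target > 0, t_alpha > 0, t_alpha < 1)
  structure(
    list(mode = mode, data_window_min = data_window_min,
         switch_discard_min = switch_discard_min,
         block_duration_min = block_duration_min, agc_target = agc_target,
         c_n = c_n, r_n = r_n, t_alpha = t_alpha,
         sem_method = match.arg(sem_method),
         ci_method = match.arg(ci_method),
         pathway_tag = if (is.null(pathway_tag)) mode else pathway_tag),
    class = "run_config"
  )
}

#' Read a run configuration from a JSON file
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults, unknown keys are an error.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "))
  do.call(run_config, cfg)
}

.SCAN_COLUMNS <- c("scan", "time", "isotopolog", "intensity", "peaknoise",
                   "resolution", "microscans")

#' Read a scan-level isotopologue observation table
#'
#' Reads a delimited export of per-scan isotopologue peaks (one row per scan
#' x isotopologue). Tab- and comma-separated files are both accepted and
#' headers are matched case-insensitively. Mandatory columns: `scan`,
#' `time` (minutes), `isotopolog`, `intensity`, `peakNoise`, `resolution`,
#' `microscans`. Optional: `charge` (default 1), `source` (default the file
#' name). Rows whose `isotopolog` label is not in the catalog are dropped
#' with a warning stating the count; the number is also available as
#' `attr(x, "rows_rejected")`.
#'
#' @param path File path.
#' @param catalog Isotopologue catalog (named list of [iso_spec()]), default
#'   [smx_catalog()].
#' @return A data.frame with columns `source_id`, `scan`, `time.min`,
#'   `isotopolog`, `intensity`, `peakNoise`, `resolution`, `microscans`,
#'   `charge`, sorted by source and time.
#' @export
read_scan_table <- function(path, catalog = smx_catalog()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(raw))
  miss <- setdiff(.SCAN_COLUMNS, lc)
  if (length(miss))
    stop("scan table ", path, " missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  col <- function(nm) raw[[which(lc == nm)[1]]]
  num_col <- function(nm) {
    v <- col(nm)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", nm, "' at data row ", bad[1])
    out
  }
  scans <- data.frame(
    source_id = if ("source" %in% lc) as.character(col("source"))
                else basename(path),
    scan = as.integer(num_col("scan")),
    time.min = num_col("time"),
    isotopolog = as.character(col("isotopolog")),
    intensity = num_col("intensity"),
    peakNoise = num_col("peaknoise"),
    resolution = num_col("resolution"),
    microscans = as.integer(num_col("microscans")),
    charge = if ("charge" %in% lc) as.integer(num_col("charge")) else 1L,
    stringsAsFactors = FALSE
  )
  if (any(scans$intensity < 0)) stop("negative intensity in ", path)
  if (any(scans$peakNoise <= 0)) stop("non-positive peakNoise in ", path)
  if (any(scans$resolution <= 0)) stop("non-positive resolution in ", path)
  if (any(scans$microscans < 1)) stop("microscans < 1 in ", path)
  known <- names(catalog)
  keep <- scans$isotopolog %in% known
  n_rej <- sum(!keep)
  if (n_rej > 0)
    warning(n_rej, " row(s) with isotopologue labels not in the catalog ",
            "were rejected (", paste(unique(scans$isotopolog[!keep]),
                                     collapse = ", "), ")")
  scans <- scans[keep, , drop = FALSE]
  scans <- scans[order(scans$source_id, scans$time.min, scans$scan), ,
                 drop = FALSE]
  rownames(scans) <- NULL
  attr(scans, "rows_rejected") <- n_rej
  scans
}

#' Write a delta-value results table
#'
#' Tab-separated with columns `fragment`, `element`, `delta.permil`,
#' `sigma.permil`, `ci95.permil`, `n`, `mode`, `estimator`. Rereading with
#' [read_results_table()] reproduces the numbers to 6 decimals.
#'
#' @param results Results data.frame (see [process_sequence()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(results, path) {
  cols <- c("fragment", "element", "delta.permil", "sigma.permil",
            "ci95.permil", "n", "mode", "estimator")
  out <- if (nrow(results) == 0L) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                    cols)
  } else {
    res <- results
    for (cc in setdiff(cols, names(res))) res[[cc]] <- NA
    num <- c("delta.permil", "sigma.permil", "ci95.permil")
    res[num] <- lapply(res[num], function(v) sprintf("%.6f", v))
    res[cols]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path File path.
#' @return Results data.frame.
#' @export
read_results_table <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (cc in intersect(c("delta.permil", "sigma.permil", "ci95.permil"),
                       names(res)))
    res[[cc]] <- as.numeric(res[[cc]])
  res
}

#' Read an EA-IRMS bulk-value / standards table
#'
#' Tab- or comma-separated with case-insensitive columns `standard_id`,
#' `fragment` (labeled fragment), `element`, `delta_bulk_shift` (per mil vs
#' the unlabeled working reference) and `sd` (per mil); optional
#' `n_replicates`.
#'
#' @param path File path.
#' @return Data.frame of standard definitions.
#' @export
read_standards_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("standard_id", "fragment", "element", "delta_bulk_shift", "sd")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("standards table missing column(s): ", paste(miss, collapse = ", "))
  if (any(raw$sd < 0)) stop("negative sd in standards table")
  raw
}
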