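# Ion-count estimation from signal-to-noise and window-aggregated
# isotopologue ratios.

#' Estimated number of ions observed per scan
#'
#' Converts an Orbitrap peak's signal-to-noise ratio into an estimated ion
#' count:
#' \deqn{N_{IO} = \frac{S}{N}\,\frac{C_N}{z}\,\sqrt{R_N/R}\,\sqrt{\mu}}
#' where S is the ion intensity, N the peak noise, C_N an empirical
#' noise-band constant (default 3), z the charge, R_N the reference
#' resolution (default 240,000), R the nominal resolution of the scan, and
#' mu the number of microscans averaged per stored spectrum. All arguments
#' are vectorized.
#'
#' @param intensity Ion intensity S (>= 0).
#' @param peak_noise Peak noise N (> 0, same units as S).
#' @param resolution Nominal resolution R (> 0).
#' @param microscans Microscans mu (>= 1).
#' @param charge Charge z (default 1).
#' @param c_n Empirical constant (default 3).
#' @param r_n Reference resolution (default 240000).
#' @return Estimated ion count(s).
#' @export
#' @examples
#' ions_per_scan(100, 1, 90000, 10)  # 100 * 15.4919... = 1549.19
ions_per_scan <- function(intensity, peak_noise, resolution, microscans,
                          charge = 1, c_n = 3, r_n = 240000) {
  if (any(peak_noise <= 0)) stop("peak_noise must be positive")
  if (any(resolution <= 0)) stop("resolution must be positive")
  if (any(microscans < 1)) stop("microscans must be >= 1")
  if (c_n <= 0 || r_n <= 0) stop("C_N and R_N must be positive")
  (intensity / peak_noise) * (c_n / charge) *
    sqrt(r_n / resolution) * sqrt(microscans)
}

#' Add estimated ion counts to a scan table
#'
#' @param scans Scan table (see [read_scan_table()]).
#' @param config Run configuration ([run_config()]); supplies C_N and R_N.
#'   mu, R and z are taken per scan from the table.
#' @return The scan table with an `n_io` column appended.
#' @export
add_ion_counts <- function(scans, config = run_config()) {
  scans$n_io <- ions_per_scan(scans$intensity, scans$peakNoise,
                              scans$resolution, scans$microscans,
                              charge = scans$charge,
                              c_n = config$c_n, r_n = config$r_n)
  scans
}

#' Restrict observations to a time window
#'
#' Half-open convention: scans with `start <= time < end` are kept.
#'
#' @param scans Scan table with a `time.min` column.
#' @param window Numeric `c(start, end)` in minutes, start < end.
#' @return Filtered scan table; empty selection is an error.
#' @export
select_window <- function(scans, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- scans$time.min >= window[1] & scans$time.min < window[2]
  if (!any(keep))
    stop(sprintf("no scans in window [%g, %g) min", window[1], window[2]))
  scans[keep, , drop = FALSE]
}

#' Window-aggregated isotopologue ratio
#'
#' The point estimate is the ratio of summed ion counts over the window,
#' \eqn{R^i = \sum_j N_{IO}(i) / \sum_j N_{IO}(base)}, which equals the
#' count-weighted mean of per-scan ratios. Its standard error is, by
#' default, the standard error of the mean of the per-scan ratios
#' (`sem_method = "scan"`); `sem_method = "bootstrap"` resamples scans
#' instead (B = 200, seeded from the current RNG state).
#'
#' Scans where the numerator species was not detected contribute zero counts
#' (they are not dropped); scans missing the base peak are an error.
#'
#' @param counts_i Numeric vector of per-scan counts of isotopologue i.
#' @param counts_base Per-scan counts of the base peak, same scans in the
#'   same order.
#' @param sem_method `"scan"` (default) or `"bootstrap"`.
#' @param labels Optional `c(numerator, basepeak)` labels carried through.
#' @return A list of class `ratio_result`: `ratio`, `sem`, `n_scans`,
#'   `numerator_label`, `basepeak_label`.
#' @export
window_ratio <- function(counts_i, counts_base,
                         sem_method = c("scan", "bootstrap"),
                         labels = c("i", "base")) {
  sem_method <- match.arg(sem_method)
  if (length(counts_i) != length(counts_base))
    stop("mismatched scan sets: ", length(counts_i), " vs ",
         length(counts_base), " scans")
  if (any(counts_i < 0) || any(counts_base < 0))
    stop("ion counts must be non-negative")
  tot_base <- sum(counts_base)
  if (tot_base == 0) stop("base peak sum is zero: ratio undefined")
  ratio <- sum(counts_i) / tot_base
  n <- length(counts_i)
  ok <- counts_base > 0
  if (sem_method == "scan") {
    r_scan <- counts_i[ok] / counts_base[ok]
    sem <- if (sum(ok) > 1) stats::sd(r_scan) / sqrt(sum(ok)) else 0
  } else {
    boot <- replicate(200, {
      idx <- sample.int(n, n, replace = TRUE)
      sum(counts_i[idx]) / max(sum(counts_base[idx]), .Machine$double.eps)
    })
    sem <- stats::sd(boot)
  }
  structure(
    list(ratio = ratio, sem = sem, n_scans = n,
         numerator_label = labels[1], basepeak_label = labels[2]),
    class = "ratio_result"
  )
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio %s/%s = %.6g +/- %.2g (n=%d scans)>\n",
              x$numerator_label, x$basepeak_label, x$ratio, x$sem, x$n_scans))
  invisible(x)
}

# Per (fragment, element) window ratio from a labeled scan table.
# Returns ratio_result; scans aligned on scan index within one source.
pair_window_ratio <- function(scans, label_num, label_base, config) {
  num <- scans[scans$isotopolog == label_num, , drop = FALSE]
  base <- scans[scans$isotopolog == label_base, , drop = FALSE]
  if (nrow(base) == 0L) stop("no base-peak scans for ", label_base)
  idx <- sort(unique(base$scan))
  ci <- numeric(length(idx))
  ci[match(num$scan, idx)] <- num$n_io      # absent numerator scans -> 0
  cb <- base$n_io[match(idx, base$scan)]
  window_ratio(ci, cb, sem_method = config$sem_method,
               labels = c(label_num, label_base))
}
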