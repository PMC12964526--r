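# Sample-standard bracketing: block segmentation, reference averaging, and
# delta / delta-shift computation.

#' Segment a measurement timeline into alternating blocks
#'
#' Cuts the scan timeline into consecutive blocks of
#' `config$block_duration_min` starting at t = 0, alternating
#' reference/sample with the first block a reference (the syringe-infusion
#' standard). The first `config$switch_discard_min` minutes of each block
#' (valve switching) are excluded from the usable span, so block k is usable
#' on `[k d + s, (k+1) d)`. A trailing partial block is dropped with a
#' warning; fewer than 3 complete blocks (no complete
#' reference-sample-reference bracket) is an error.
#'
#' @param scans Scan table.
#' @param config A [run_config()] with `mode = "lc_blocks"`.
#' @return Data.frame with columns `index` (1-based), `role`, `start`,
#'   `end`, `usable_start`, `usable_end` (minutes).
#' @export
segment_blocks <- function(scans, config = run_config()) {
  if (config$mode != "lc_blocks")
    stop("segment_blocks applies to lc_blocks mode; use block_plan() for ",
         "direct infusion")
  d <- config$block_duration_min
  t_max <- max(scans$time.min)
  n_blocks <- floor(t_max / d) + 1L
  # partial trailing block: coverage stops well short of its end
  if (t_max < n_blocks * d - 0.5 && n_blocks > 1L) {
    warning("trailing partial block dropped (coverage ends at ",
            round(t_max, 2), " min)")
    n_blocks <- n_blocks - 1L
  }
  if (n_blocks < 3L)
    stop("only ", n_blocks, " complete block(s): no complete ",
         "reference-sample-reference bracket")
  k <- seq_len(n_blocks) - 1L
  roles <- ifelse(k %% 2L == 0L, "reference", "sample")
  if (roles[n_blocks] == "sample")
    warning("sequence ends on a sample block with no trailing reference; ",
            "that block cannot be bracketed")
  data.frame(
    index = k + 1L, role = roles,
    start = k * d, end = (k + 1) * d,
    usable_start = k * d + config$switch_discard_min,
    usable_end = (k + 1) * d,
    stringsAsFactors = FALSE
  )
}

#' Explicit block plan (direct-infusion sequences)
#'
#' In direct infusion each injection is one block and roles come from the
#' injection sequence (e.g. reference-sample-reference triplets), not from
#' the clock. The usable span of each block starts after
#' `switch_discard_min` and extends for at most `data_window_min`.
#'
#' @param roles Character vector of `"reference"` / `"sample"` in injection
#'   order.
#' @param config A [run_config()]; supplies durations and windows.
#' @param duration_min Injection block duration (default
#'   `config$block_duration_min`).
#' @return Block data.frame as in [segment_blocks()].
#' @export
block_plan <- function(roles, config = run_config(mode = "direct_infusion"),
                       duration_min = config$block_duration_min) {
  stopifnot(all(roles %in% c("reference", "sample")), length(roles) >= 3L)
  k <- seq_along(roles) - 1L
  us <- k * duration_min + config$switch_discard_min
  data.frame(
    index = k + 1L, role = roles,
    start = k * duration_min, end = (k + 1) * duration_min,
    usable_start = us,
    usable_end = pmin(us + config$data_window_min, (k + 1) * duration_min),
    stringsAsFactors = FALSE
  )
}

#' Average the two bracketing reference ratios
#'
#' Arithmetic mean of the reference ratios measured before and after a
#' sample, with the propagated uncertainty
#' \deqn{\sigma_{ref} = \sqrt{(\sigma_1/2)^2 + (\sigma_2/2)^2}}
#'
#' @param before,after `ratio_result` objects ([window_ratio()]) for the
#'   same isotopologue pair. One-sided bracketing is not allowed.
#' @return List with `ratio` and `sigma`.
#' @export
reference_average <- function(before, after) {
  if (is.null(before) || is.null(after))
    stop("missing bracket: both a before and an after reference are required")
  if (!identical(before$numerator_label, after$numerator_label) ||
      !identical(before$basepeak_label, after$basepeak_label))
    stop("bracketing references computed on different isotopologue pairs")
  list(ratio = (before$ratio + after$ratio) / 2,
       sigma = sqrt((before$sem / 2)^2 + (after$sem / 2)^2))
}

#' Delta value of a sample ratio against a reference ratio
#'
#' \deqn{\delta = (R_{sample}/R_{reference} - 1) \times 1000} per mil.
#'
#' @param R_sample Sample isotope (or isotopologue) ratio.
#' @param R_reference Reference ratio (> 0).
#' @return Delta in per mil; vectorized.
#' @export
delta_permil <- function(R_sample, R_reference) {
  if (any(R_reference <= 0)) stop("reference ratio must be positive")
  (R_sample / R_reference - 1) * 1000
}

#' Shift between two delta values
#'
#' \eqn{\Delta\delta = \delta_{sample} - \delta_{reference}}. With the
#' bracketing working reference arbitrarily set to 0 per mil, the
#' reference's own shift is 0 and a sample's shift equals its delta.
#'
#' @param delta_sample,delta_reference Delta values, per mil.
#' @param element_sample,element_reference Optional element symbols; a
#'   mismatch is an error.
#' @return Delta shift in per mil.
#' @export
delta_shift <- function(delta_sample, delta_reference,
                        element_sample = NULL, element_reference = NULL) {
  if (!is.null(element_sample) && !is.null(element_reference) &&
      !identical(element_sample, element_reference))
    stop("element mismatch: ", element_sample, " vs ", element_reference)
  delta_sample - delta_reference
}

#' Process a bracketed measurement sequence into delta shifts
#'
#' Runs the full scan-level chain: ion counts from signal-to-noise, usable
#' window selection per block, window-aggregated isotopologue ratios, mean
#' of the two bracketing reference ratios, delta per bracket, Gaussian
#' propagation of the ratio errors, and aggregation of the n sample brackets
#' into a delta shift with a 95% CI. Because the working reference is set to
#' 0 per mil, the reported delta IS the delta shift vs the reference.
#'
#' With a single sample bracket (n = 1) the CI is the z-based
#' 1.96 x sigma of that bracket; with n >= 2 the configured estimator
#' applies (`rms_t`: RMS of bracket sigmas x Student t at n-1 df;
#' `replicate_sd`: dispersion of the bracket deltas).
#'
#' @param scans Scan table ([read_scan_table()] schema).
#' @param config A [run_config()].
#' @param catalog Isotopologue catalog.
#' @param blocks Block table; derived via [segment_blocks()] when `NULL`
#'   and mode is `lc_blocks`. Required for direct infusion
#'   ([block_plan()]).
#' @return Data.frame with one row per (fragment, element): `fragment`,
#'   `element`, `delta.permil`, `sigma.permil` (RMS of bracket sigmas),
#'   `ci95.permil`, `n` (brackets), `mode`, `estimator`. Per-bracket detail
#'   is attached as `attr(x, "brackets")`.
#' @export
process_sequence <- function(scans, config = run_config(),
                             catalog = smx_catalog(), blocks = NULL) {
  if (is.null(blocks)) {
    if (config$mode != "lc_blocks")
      stop("blocks must be supplied (block_plan) in direct_infusion mode")
    blocks <- segment_blocks(scans, config)
  }
  scans <- add_ion_counts(scans, config)
  pairs <- catalog_pairs(catalog)

  # per-block window ratios for every monitored pair
  ratios <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    win <- c(blocks$usable_start[b], blocks$usable_end[b])
    sub <- select_window(scans, win)
    ratios[[b]] <- lapply(seq_len(nrow(pairs)), function(p)
      pair_window_ratio(sub, pairs$label[p], pairs$base_label[p], config))
  }

  sample_idx <- which(blocks$role == "sample")
  usable <- sample_idx[vapply(sample_idx, function(b) {
    b > 1L && b < nrow(blocks) &&
      blocks$role[b - 1L] == "reference" && blocks$role[b + 1L] == "reference"
  }, logical(1))]
  if (length(usable) == 0L)
    stop("no sample block with a reference on both sides")
  if (length(usable) < length(sample_idx))
    warning(length(sample_idx) - length(usable),
            " sample block(s) without full brackets were skipped")

  detail <- list()
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    deltas <- sigmas <- numeric(length(usable))
    for (i in seq_along(usable)) {
      b <- usable[i]
      rs <- ratios[[b]][[p]]
      ref <- reference_average(ratios[[b - 1L]][[p]], ratios[[b + 1L]][[p]])
      d <- delta_permil(rs$ratio, ref$ratio)
      deltas[i] <- delta_shift(d, 0)            # working reference at 0
      sigmas[i] <- propagate_delta_sigma(rs$sem, rs$ratio,
                                         ref$ratio, ref$sigma)
      detail[[length(detail) + 1L]] <- data.frame(
        fragment = pairs$fragment[p], element = pairs$element[p],
        block = blocks$index[b], delta.permil = deltas[i],
        sigma.permil = sigmas[i], stringsAsFactors = FALSE)
    }
    n <- length(usable)
    ci <- if (n == 1L) {
      1.96 * sigmas
    } else if (config$ci_method == "rms_t") {
      ci95(sigmas, config$t_alpha)
    } else {
      ci95_replicate_sd(deltas, config$t_alpha)
    }
    rows[[p]] <- data.frame(
      fragment = pairs$fragment[p], element = pairs$element[p],
      delta.permil = mean(deltas), sigma.permil = sqrt(mean(sigmas^2)),
      ci95.permil = ci, n = n, mode = config$mode,
      estimator = if (n == 1L) "z" else config$ci_method,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "brackets") <- do.call(rbind, detail)
  out
}
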