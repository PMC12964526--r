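# Calibration of measured delta shifts against labeled in-house standards
# characterized by EA-IRMS.

#' Define a labeled in-house standard
#'
#' A standard is unlabeled compound spiked with material labeled at one
#' position inside one fragment. Its EA-IRMS bulk shift (vs the unlabeled
#' working reference) determines the expected fragment enrichment through
#' atom-count mass balance ([fragment_calc_from_bulk()]); all other
#' fragment/element combinations are expected at 0.
#'
#' @param standard_id Identifier, e.g. `"A3"`.
#' @param fragment Labeled fragment name.
#' @param element Labeled element symbol.
#' @param delta_bulk_shift EA-IRMS bulk shift, per mil.
#' @param sd EA-IRMS replicate standard deviation, per mil.
#' @param molecule A [molecule_def()], default [smx_molecule()].
#' @param n_replicates EA-IRMS replicate count.
#' @return List of class `standard_def` including the derived `delta_calc`.
#' @export
standard_def <- function(standard_id, fragment, element, delta_bulk_shift,
                         sd = 0.3, molecule = smx_molecule(),
                         n_replicates = 5L) {
  stopifnot(sd >= 0, n_replicates >= 1L)
  structure(
    list(standard_id = standard_id, fragment = fragment, element = element,
         delta_bulk_shift = delta_bulk_shift, sd = sd,
         n_replicates = as.integer(n_replicates),
         delta_calc = fragment_calc_from_bulk(delta_bulk_shift, molecule,
                                              fragment, element)),
    class = "standard_def"
  )
}

#' Linear calibration regression
#'
#' Ordinary least squares of measured delta shifts on the mass-balance
#' calculated values of the standards. Slopes may deviate from unity
#' (instrumental isotope fractionation, scale compression), which is what
#' the calibration corrects. Optionally weighted by 1/sigma^2.
#'
#' @param points Data.frame with columns `delta_calc`, `delta_measured` and
#'   optionally `sigma_measured` (per mil).
#' @param fragment,element Labels carried into the model.
#' @param weighted Use 1/sigma^2 weights (requires `sigma_measured` > 0).
#' @return Object of class `calibration_model` with `slope`, `intercept`,
#'   their standard errors, `n_points` and `kind = "regression"`.
#' @export
build_regression <- function(points, fragment = NA_character_,
                             element = NA_character_, weighted = FALSE) {
  stopifnot(is.data.frame(points), nrow(points) >= 2L,
            all(c("delta_calc", "delta_measured") %in% names(points)))
  if (length(unique(points$delta_calc)) < 2L)
    stop("degenerate abscissa: need at least 2 distinct calculated values")
  w <- NULL
  if (weighted) {
    stopifnot("sigma_measured" %in% names(points),
              all(points$sigma_measured > 0))
    w <- 1 / points$sigma_measured^2
  }
  fit <- stats::lm(delta_measured ~ delta_calc, data = points, weights = w)
  # suppress the "essentially perfect fit" note on noiseless standards
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(fragment = fragment, element = element,
         slope = unname(cf["delta_calc", "Estimate"]),
         intercept = unname(cf["(Intercept)", "Estimate"]),
         slope_se = unname(cf["delta_calc", "Std. Error"]),
         intercept_se = unname(cf["(Intercept)", "Std. Error"]),
         n_points = nrow(points), kind = "regression"),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration %s-%s (%s, n=%d): measured = %.4f x calc + %.4f>\n",
    x$fragment, x$element, x$kind, x$n_points, x$slope, x$intercept))
  invisible(x)
}

#' Two-point calibration model
#'
#' Builds the line through two standards of known (true, measured) delta
#' shifts; equivalent to [build_regression()] on the same two points.
#'
#' @param std_lo,std_hi Numeric `c(true, measured)` pairs, per mil.
#' @param fragment,element Labels carried into the model.
#' @return A `calibration_model` with `kind = "two_point"`.
#' @export
two_point_model <- function(std_lo, std_hi, fragment = NA_character_,
                            element = NA_character_) {
  stopifnot(length(std_lo) == 2L, length(std_hi) == 2L)
  if (std_lo[2] == std_hi[2])
    stop("the two standards have identical measured values")
  if (std_lo[1] == std_hi[1])
    stop("the two standards have identical true values")
  slope <- unname((std_hi[2] - std_lo[2]) / (std_hi[1] - std_lo[1]))
  structure(
    list(fragment = fragment, element = element, slope = slope,
         intercept = unname(std_lo[2] - slope * std_lo[1]),
         slope_se = NA_real_, intercept_se = NA_real_,
         n_points = 2L, kind = "two_point"),
    class = "calibration_model"
  )
}

#' Two-point calibration of a measured delta shift
#'
#' Maps a measured value onto the true scale by linear
#' interpolation/extrapolation through two standards:
#' `true_lo + (measured - meas_lo) * (true_hi - true_lo) /
#' (meas_hi - meas_lo)`.
#'
#' @param delta_measured_sample Measured delta shift, per mil.
#' @param std_lo,std_hi Numeric `c(true, measured)` pairs.
#' @return Calibrated delta shift, per mil.
#' @export
#' @examples
#' two_point_calibrate(40, c(0, 0), c(100, 80))  # 50
two_point_calibrate <- function(delta_measured_sample, std_lo, std_hi) {
  if (std_lo[2] == std_hi[2])
    stop("the two standards have identical measured values")
  std_lo[1] + (delta_measured_sample - std_lo[2]) *
    (std_hi[1] - std_lo[1]) / (std_hi[2] - std_lo[2])
}

#' Apply a calibration model to a measured value
#'
#' Inverse-maps the measured delta shift through the model,
#' `(measured - intercept) / slope`, scaling its uncertainty by `1/|slope|`
#' (first order). Standard true-value (EA-IRMS) error is not included by
#' default; see `extra_sigma_true`.
#'
#' @param model A `calibration_model`.
#' @param delta_measured Measured delta shift, per mil.
#' @param sigma_measured Its uncertainty, per mil.
#' @param extra_sigma_true Optional additional true-scale sigma added in
#'   quadrature (per mil).
#' @return List with `delta` and `sigma`, per mil.
#' @export
apply_calibration <- function(model, delta_measured, sigma_measured = 0,
                              extra_sigma_true = 0) {
  stopifnot(inherits(model, "calibration_model"))
  if (abs(model$slope) < 0.05)
    stop("calibration slope ", signif(model$slope, 3),
         " too close to zero: uncalibratable")
  delta <- (delta_measured - model$intercept) / model$slope
  sigma <- sqrt((sigma_measured / abs(model$slope))^2 + extra_sigma_true^2)
  list(delta = delta, sigma = sigma)
}

#' Principle-of-identical-treatment check
#'
#' Reference and sample must have gone through the same processing pathway
#' (same introduction route, same mode, same window) for bracketing to
#' cancel instrumental effects; e.g. a column-processed sample must be
#' referenced against a column-processed standard, not direct syringe
#' infusion.
#'
#' @param reference_pathway_tag,sample_pathway_tag Pathway tags (non-empty
#'   strings, e.g. `"lc_blocks/column"`).
#' @return `TRUE` if the tags match; `FALSE` (with a message attribute) if
#'   not. Missing tags are an error.
#' @export
identical_treatment_check <- function(reference_pathway_tag,
                                      sample_pathway_tag) {
  if (is.null(reference_pathway_tag) || is.null(sample_pathway_tag) ||
      is.na(reference_pathway_tag) || is.na(sample_pathway_tag) ||
      !nzchar(reference_pathway_tag) || !nzchar(sample_pathway_tag))
    stop("missing processing-pathway tag")
  if (identical(reference_pathway_tag, sample_pathway_tag)) return(TRUE)
  structure(FALSE, message = paste0(
    "identical-treatment violation: reference processed as '",
    reference_pathway_tag, "' but sample as '", sample_pathway_tag, "'"))
}

#' Fit calibration models per (fragment, element) from a standards table
#'
#' @param measured Data.frame with columns `standard_id`, `fragment`,
#'   `element`, `delta.permil` (measured), optionally `sigma.permil`.
#' @param standards Standards data.frame ([read_standards_table()] schema).
#' @param molecule A [molecule_def()].
#' @param min_points Minimum standards per model (default 2).
#' @return Named list of `calibration_model`s keyed `"fragment.element"`.
#' @export
build_calibrations <- function(measured, standards,
                               molecule = smx_molecule(), min_points = 2L) {
  keys <- unique(paste(measured$fragment, measured$element, sep = "."))
  models <- list()
  for (key in keys) {
    fe <- strsplit(key, ".", fixed = TRUE)[[1]]
    std <- standards[standards$fragment == fe[1] &
                     standards$element == fe[2], , drop = FALSE]
    mm <- measured[measured$fragment == fe[1] & measured$element == fe[2], ,
                   drop = FALSE]
    mm <- mm[mm$standard_id %in% std$standard_id, , drop = FALSE]
    if (nrow(mm) < min_points)
      stop("insufficient standards for model ", key, ": have ", nrow(mm),
           ", need ", min_points)
    calc <- vapply(seq_len(nrow(mm)), function(i) {
      s <- std[std$standard_id == mm$standard_id[i], ]
      fragment_calc_from_bulk(s$delta_bulk_shift[1], molecule, fe[1], fe[2])
    }, numeric(1))
    pts <- data.frame(delta_calc = calc, delta_measured = mm$delta.permil)
    models[[key]] <- if (nrow(pts) == 2L) {
      o <- order(pts$delta_calc)
      two_point_model(unlist(pts[o[1], ]), unlist(pts[o[2], ]),
                      fragment = fe[1], element = fe[2])
    } else {
      build_regression(pts, fragment = fe[1], element = fe[2])
    }
  }
  models
}
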