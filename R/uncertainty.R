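# Error propagation: ratio sigma -> delta sigma, and replicate sigmas -> 95% CI.

#' Propagate ratio uncertainties to a delta-value uncertainty
#'
#' Gaussian (first-order) propagation of the standard errors of the sample
#' ratio and the bracketing-average reference ratio into the standard error
#' of the delta value:
#' \deqn{\sigma_\delta = \sqrt{(\sigma_s / \bar R_r)^2 +
#'       (R_s \sigma_r / \bar R_r^2)^2} \times 1000}
#' The result is in per mil, on the same footing as
#' `delta_permil(R_sample, R_ref_avg)`.
#'
#' @param sigma_sample Standard error of the sample ratio (>= 0).
#' @param R_sample Sample isotopologue ratio.
#' @param R_ref_avg Bracketing-average reference ratio (> 0).
#' @param sigma_ref_avg Standard error of the reference average (>= 0).
#' @return Sigma of the delta value, per mil.
#' @export
propagate_delta_sigma <- function(sigma_sample, R_sample, R_ref_avg,
                                  sigma_ref_avg) {
  if (any(c(sigma_sample, sigma_ref_avg) < 0))
    stop("sigmas must be non-negative")
  if (R_ref_avg <= 0) stop("reference ratio must be positive")
  1000 * sqrt((sigma_sample / R_ref_avg)^2 +
              (R_sample * sigma_ref_avg / R_ref_avg^2)^2)
}

#' Two-sided Student t critical value
#'
#' @param n Number of replicates (>= 2); the critical value is taken at
#'   n - 1 degrees of freedom.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Critical value t_{alpha, n-1}; 2.776 for n = 5, 3.182 for n = 4.
#' @export
t_factor <- function(n, alpha = 0.05) {
  if (n < 2) stop("t_factor requires n >= 2")
  stats::qt(1 - alpha / 2, df = n - 1)
}

#' 95% confidence interval from per-bracket sigmas
#'
#' Aggregates the propagated delta sigmas of the n reference-sample brackets
#' into a confidence half-width as the root-mean-square of the sigmas times
#' the Student t factor at n - 1 degrees of freedom:
#' \deqn{\sigma_{CI} = \sqrt{\tfrac{1}{n}\sum \sigma_i^2}\; t_{\alpha,n-1}}
#' Note this deliberately follows the bracketing convention of the method
#' (RMS x t, no 1/sqrt(n)); it is conservative relative to a standard error
#' of the mean. See [ci95_replicate_sd()] for the conventional estimator.
#'
#' @param sigmas Vector of per-bracket sigmas, per mil (length >= 2, all
#'   >= 0).
#' @param alpha Two-sided level (default 0.05).
#' @return CI half-width, per mil.
#' @export
ci95 <- function(sigmas, alpha = 0.05) {
  n <- length(sigmas)
  if (n < 2) stop("ci95 requires at least 2 sigmas")
  if (any(sigmas < 0)) stop("sigmas must be non-negative")
  sqrt(mean(sigmas^2)) * t_factor(n, alpha)
}

#' Conventional replicate-dispersion 95% CI (alternative estimator)
#'
#' Standard deviation of the replicate delta values over sqrt(n), times the
#' Student t factor: the usual CI of a mean. Offered alongside [ci95()];
#' results flag which estimator produced them.
#'
#' @param deltas Replicate delta values, per mil (length >= 2).
#' @param alpha Two-sided level.
#' @return CI half-width, per mil.
#' @export
ci95_replicate_sd <- function(deltas, alpha = 0.05) {
  n <- length(deltas)
  if (n < 2) stop("ci95_replicate_sd requires at least 2 replicates")
  stats::sd(deltas) / sqrt(n) * t_factor(n, alpha)
}
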