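#' Specification for a binary-outcome MR power calculation
#'
#' @param n_cases,n_controls Case and control counts (> 0).
#' @param r2 Fraction of exposure variance explained by the instrument,
#'   in (0, 1).  Default 0.02: the four-SNP 25(OH)D score explains about
#'   2% of the variance in circulating levels.
#' @param alpha Two-sided significance level, in (0, 1).
#' @param power Target power, in (0, 1); used by [detectable_or()].
#' @return List of class `power_spec`.
#' @export
power_spec <- function(n_cases, n_controls, r2 = 0.02, alpha = 0.05,
                       power = 0.8) {
  stopifnot(n_cases > 0, n_controls > 0,
            r2 > 0, r2 < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(n_cases = n_cases, n_controls = n_controls, r2 = r2,
                 alpha = alpha, power = power), class = "power_spec")
}

#' @keywords internal
.power_denominator <- function(spec) {
  n <- spec$n_cases + spec$n_controls
  k <- spec$n_cases / n
  sqrt(n * spec$r2 * k * (1 - k))
}

#' Smallest detectable odds ratios at a target power
#'
#' Normal-approximation power for summary-level MR with a binary outcome:
#' the detectable log odds ratio per unit exposure satisfies
#' `|log OR| = (z_{1-alpha/2} + z_{power}) / sqrt(N r2 K (1-K))`, with N
#' the total sample size and K the case fraction.  Returns the harmful
#' and protective bounds `exp(+|logOR|)` and `exp(-|logOR|)`.
#'
#' @param spec A [power_spec()].
#' @return Named numeric vector `c(or_harmful, or_protective)`.
#' @examples
#' # the all-glioma analysis: 12,488 cases, 18,169 controls, r2 = 2%
#' detectable_or(power_spec(12488, 18169))
#' @export
detectable_or <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  za <- stats::qnorm(1 - spec$alpha / 2)
  zp <- stats::qnorm(spec$power)
  if (za + zp <= 0) {
    stop("target power too low: detectable effect undefined (z_alpha + z_power <= 0)")
  }
  l <- (za + zp) / .power_denominator(spec)
  c(or_harmful = exp(l), or_protective = exp(-l))
}

#' Power to detect a given odds ratio
#'
#' Inverse of [detectable_or()]:
#' `power = Phi(sqrt(N r2 K (1-K)) |log OR| - z_{1-alpha/2})`.
#'
#' @param spec A [power_spec()] (its `power` field is ignored).
#' @param or_ Odds ratio per unit exposure (> 0).
#' @return Power in (0, 1).
#' @export
power_at_or <- function(spec, or_) {
  stopifnot(inherits(spec, "power_spec"), or_ > 0)
  za <- stats::qnorm(1 - spec$alpha / 2)
  stats::pnorm(.power_denominator(spec) * abs(log(or_)) - za)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests (>= 1); here 3 tumour classifications
#'   (all glioma, GBM, non-GBM) giving 0.05/3 ~ 0.017.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}
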