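#' Odds ratio, confidence interval and P value from a log-OR and SE
#'
#' Standard Wald summary on the odds-ratio scale: OR = exp(beta),
#' CI = exp(beta -/+ z_{1-alpha/2} * se), two-sided normal P.
#'
#' @param beta Log odds ratio.
#' @param se Standard error of `beta` (> 0).
#' @param alpha Two-sided significance level; default 0.05 (95% CI).
#' @return Named list: `or`, `ci_low`, `ci_high`, `p`.
#' @examples
#' wald_summary(0.189, 0.148)   # all-glioma scale: OR 1.21
#' @export
wald_summary <- function(beta, se, alpha = 0.05) {
  if (se <= 0) stop("se must be > 0")
  z <- stats::qnorm(1 - alpha / 2)
  list(
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    # floored at the smallest positive double so p stays in (0, 1]
    p = max(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  )
}

#' @keywords internal
new_mr_estimate <- function(method, beta, se, n_snps, alpha = 0.05) {
  ws <- wald_summary(beta, se, alpha)
  structure(
    list(method = method, beta = beta, se = se,
         or = ws$or, ci_low = ws$ci_low, ci_high = ws$ci_high,
         p = ws$p, n_snps = n_snps, alpha = alpha),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate [%s, %d SNP%s]\n  beta = %.3f  SE = %.3f\n  OR %.2f (%.2f-%.2f)  P = %.3g\n",
    x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
    x$beta, x$se, x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' @keywords internal
.active_instruments <- function(instruments) {
  if ("action" %in% names(instruments)) {
    instruments <- instruments[instruments$action != "excluded", , drop = FALSE]
  }
  if (nrow(instruments) == 0) stop("no non-excluded instruments")
  stopifnot(all(instruments$sigma_y > 0))
  instruments
}

#' Inverse-variance weighted causal estimate
#'
#' Fixed-effects IVW combination of per-SNP Wald ratios:
#' beta = sum(x y / sigma_y^2) / sum(x^2 / sigma_y^2), with
#' se = sqrt(1 / sum(x^2 / sigma_y^2)).  Equivalent to weighted linear
#' regression of y on x through the origin with weights 1/sigma_y^2.
#' Exposure-side standard errors are ignored (the no-measurement-error
#' approximation); at a single SNP this is the Wald ratio y/x with
#' se = sigma_y/|x|.
#'
#' @param instruments Harmonized instrument data.frame with columns `x`,
#'   `y`, `sigma_y` (rows with `action == "excluded"` are dropped).
#' @param alpha CI level; default 0.05.
#' @return An `mr_estimate` (method `"IVW"`).
#' @export
ivw_estimate <- function(instruments, alpha = 0.05) {
  d <- .active_instruments(instruments)
  w <- d$sigma_y^-2
  denom <- sum(d$x^2 * w)
  if (denom == 0) stop("degenerate instruments: all exposure effects are zero")
  beta <- sum(d$x * d$y * w) / denom
  se <- sqrt(1 / denom)
  new_mr_estimate("IVW", beta, se, nrow(d), alpha)
}

#' @keywords internal
.mle_nll <- function(par, x, sx, y, sy) {
  beta <- par[1]; xi <- par[-1]
  sum((x - xi)^2 / (2 * sx^2)) + sum((y - beta * xi)^2 / (2 * sy^2))
}

#' @keywords internal
.mle_grad <- function(par, x, sx, y, sy) {
  beta <- par[1]; xi <- par[-1]
  ry <- (y - beta * xi) / sy^2
  c(-sum(xi * ry), -(x - xi) / sx^2 - beta * ry)
}

#' Bivariate-normal maximum-likelihood causal estimate
#'
#' Maximizes the likelihood of the errors-in-variables model
#' `x_k ~ N(xi_k, sigma_x_k^2)`, `y_k ~ N(beta * xi_k, sigma_y_k^2)`
#' (independent across and within SNPs) over the true exposure effects
#' `xi_1..xi_K` and the causal slope `beta`, using [stats::optim()]
#' (BFGS with analytic gradient, initialised at the IVW solution with
#' `xi_k = x_k`; up to 3 jittered restarts).  Unlike IVW, this accounts
#' for exposure-side measurement error.  `se(beta)` comes from the
#' observed information: a numerical Hessian at the optimum
#' ([stats::optimHess()], central differences with magnitude-scaled
#' steps), reduced by the Schur complement against the xi block.
#'
#' @inheritParams ivw_estimate
#' @param opts Optional list: `maxit` (default 500), `reltol` (1e-12),
#'   `restarts` (3), `grad_tol` (1e-8, scaled by the total weight).
#' @param diagnostics If `TRUE` return `list(estimate, fit)` where `fit`
#'   carries `xi`, `loglik`, `converged` and the optimizer trace.
#' @return An `mr_estimate` (method `"MLE"`), or a list when
#'   `diagnostics = TRUE`.
#' @export
mle_estimate <- function(instruments, alpha = 0.05, opts = list(),
                         diagnostics = FALSE) {
  d <- .active_instruments(instruments)
  stopifnot(all(d$sigma_x > 0))
  o <- utils::modifyList(
    list(maxit = 500L, reltol = 1e-12, restarts = 3L, grad_tol = 1e-8), opts)
  x <- d$x; sx <- d$sigma_x; y <- d$y; sy <- d$sigma_y
  k <- length(x)

  beta0 <- ivw_estimate(d, alpha)$beta
  start <- c(beta0, x)
  parscale <- c(max(abs(beta0), 0.1), pmax(sx, 1e-8))
  ctrl <- list(maxit = o$maxit, reltol = o$reltol, parscale = parscale)
  # gradient tolerance scaled by the problem's total precision weight
  tol <- o$grad_tol * (1 + sum(1 / sy^2) + sum(1 / sx^2))

  fit <- NULL; trace <- character(0)
  for (attempt in seq_len(o$restarts + 1L)) {
    f <- stats::optim(start, .mle_nll, .mle_grad, x = x, sx = sx, y = y,
                      sy = sy, method = "BFGS", control = ctrl)
    g <- max(abs(.mle_grad(f$par, x, sx, y, sy)))
    trace <- c(trace, sprintf("attempt %d: convergence=%d nll=%.6g max|grad|=%.3g",
                              attempt, f$convergence, f$value, g))
    if (f$convergence == 0 && g <= tol) { fit <- f; break }
    jitter <- stats::rnorm(k + 1, 0, 0.05 * parscale)
    start <- f$par + jitter
  }
  if (is.null(fit)) {
    stop("MLE did not converge after restarts:\n",
         paste(trace, collapse = "\n"))
  }

  h <- stats::optimHess(fit$par, .mle_nll, .mle_grad, x = x, sx = sx,
                        y = y, sy = sy, control = list(parscale = parscale))
  # Schur complement of the (diagonal-dominant) xi block: stable as sigma_x -> 0
  hbb <- h[1, 1]; hbx <- h[1, -1]; dxx <- diag(h)[-1]
  info_beta <- hbb - sum(hbx^2 / dxx)
  if (!is.finite(info_beta) || info_beta <= 0) {
    stop("observed information for beta is not positive definite")
  }
  se_beta <- sqrt(1 / info_beta)

  est <- new_mr_estimate("MLE", fit$par[1], se_beta, k, alpha)
  if (!diagnostics) return(est)
  ll <- -fit$value - sum(log(2 * pi * sx^2)) / 2 - sum(log(2 * pi * sy^2)) / 2
  list(estimate = est,
       fit = list(beta = fit$par[1], xi = fit$par[-1], loglik = ll,
                  converged = TRUE, se_beta = se_beta, trace = trace))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects
#' *with* an unconstrained intercept, weights 1/sigma_y^2, after
#' orienting every instrument so that x_k >= 0 (negating y_k in tandem).
#' The slope is a causal estimate robust to directional pleiotropy under
#' the InSIDE assumption; the intercept estimates the average direct
#' (pleiotropic) effect — zero under no or balanced pleiotropy.
#'
#' Standard errors use the multiplicative residual error model standard
#' for MR-Egger: unscaled weighted-least-squares covariance multiplied by
#' max(1, residual standard deviation), so balanced pleiotropy inflates
#' the SEs rather than biasing the test.  P values are two-sided normal
#' by default; set `t_dist = TRUE` for a t reference with K - 2 df.
#'
#' @inheritParams ivw_estimate
#' @param t_dist Use a t(K-2) reference distribution instead of normal.
#' @return List of class `mr_egger`: `slope` (an `mr_estimate`, method
#'   `"Egger_slope"`), `intercept` (list `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`), `n_snps`, `residual_scale`.
#' @export
egger_regression <- function(instruments, alpha = 0.05, t_dist = FALSE) {
  d <- .active_instruments(instruments)
  k <- nrow(d)
  if (k < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- d$x < 0
  x <- ifelse(flip, -d$x, d$x)
  y <- ifelse(flip, -d$y, d$y)
  if (stats::sd(x) == 0) stop("collinear instruments: all exposure effects equal")
  w <- d$sigma_y^-2

  X <- cbind(intercept = 1, slope = x)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * y))
  cov_unscaled <- solve(xtwx)
  r <- y - X %*% coefs
  sigma2 <- sum(w * r^2) / (k - 2)
  scale <- max(1, sqrt(sigma2))
  se <- sqrt(diag(cov_unscaled)) * scale

  crit <- if (t_dist) stats::qt(1 - alpha / 2, df = k - 2) else stats::qnorm(1 - alpha / 2)
  pval <- function(est, s) {
    z <- abs(est / s)
    if (t_dist) 2 * stats::pt(-z, df = k - 2) else 2 * stats::pnorm(-z)
  }

  slope <- new_mr_estimate("Egger_slope", unname(coefs["slope", 1]),
                           unname(se["slope"]), k, alpha)
  # keep CI/P consistent with the chosen reference distribution
  slope$ci_low <- exp(slope$beta - crit * slope$se)
  slope$ci_high <- exp(slope$beta + crit * slope$se)
  slope$p <- pval(slope$beta, slope$se)

  a <- unname(coefs["intercept", 1]); sa <- unname(se["intercept"])
  structure(list(
    slope = slope,
    intercept = list(estimate = a, se = sa,
                     ci_low = a - crit * sa, ci_high = a + crit * sa,
                     p = pval(a, sa)),
    n_snps = k, residual_scale = scale
  ), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat(sprintf("MR-Egger [%d SNPs]\n", x$n_snps))
  cat(sprintf("  slope     %.3f (SE %.3f)  OR %.2f (%.2f-%.2f)  P = %.3g\n",
              x$slope$beta, x$slope$se, x$slope$or, x$slope$ci_low,
              x$slope$ci_high, x$slope$p))
  cat(sprintf("  intercept %.3f (SE %.3f)  95%% CI %.3f to %.3f  P = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$ci_low,
              x$intercept$ci_high, x$intercept$p))
  invisible(x)
}
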