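#' Fixed-effect inverse-variance meta-analysis of per-cohort MR estimates
#'
#' Pools cohort-level causal estimates under a common-effect model:
#' pooled beta = sum(w_i beta_i) / sum(w_i), pooled
#' se = sqrt(1 / sum(w_i)) with w_i = 1/se_i^2.  Cochran's Q and I^2 are
#' computed as heterogeneity diagnostics but never gate results.
#'
#' @param estimates Either a data.frame with columns `cohort`, `beta`,
#'   `se` (optionally `n_snps`), or a named list of `mr_estimate`
#'   objects keyed by cohort label.
#' @param method Label for the per-cohort estimator being pooled
#'   (taken from the estimates when available).
#' @param subtype Outcome subtype label carried through to the result.
#' @param alpha CI level for the pooled estimate.
#' @return Object of class `mr_meta`: `pooled` (an `mr_estimate`),
#'   `components` (data.frame `cohort`, `beta`, `se`, `weight` with
#'   weights normalized to sum 1), `method`, `subtype`, `Q`, `I2`.
#' @export
fixed_effect_meta <- function(estimates, method = NULL, subtype = NA_character_,
                              alpha = 0.05) {
  if (is.data.frame(estimates)) {
    d <- estimates
    if (is.null(method)) method <- if ("method" %in% names(d)) d$method[1] else "pooled"
    n_snps <- if ("n_snps" %in% names(d)) max(d$n_snps) else NA_integer_
  } else {
    stopifnot(length(estimates) >= 1)
    if (is.null(method)) method <- estimates[[1]]$method
    d <- data.frame(
      cohort = names(estimates),
      beta = vapply(estimates, `[[`, numeric(1), "beta"),
      se = vapply(estimates, `[[`, numeric(1), "se"),
      stringsAsFactors = FALSE
    )
    n_snps <- max(vapply(estimates, `[[`, numeric(1), "n_snps"))
  }
  if (nrow(d) == 0) stop("no estimates to pool")
  stopifnot(all(d$se > 0))

  w <- d$se^-2
  beta_p <- sum(w * d$beta) / sum(w)
  se_p <- sqrt(1 / sum(w))
  q <- sum(w * (d$beta - beta_p)^2)
  i2 <- if (nrow(d) > 1 && q > 0) max(0, (q - (nrow(d) - 1)) / q) else 0

  structure(list(
    pooled = new_mr_estimate(method, beta_p, se_p, n_snps, alpha),
    components = data.frame(cohort = d$cohort, beta = d$beta, se = d$se,
                            weight = w / sum(w), stringsAsFactors = FALSE),
    method = method, subtype = subtype, Q = q, I2 = i2
  ), class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis [%s%s, %d cohorts]\n",
              x$method,
              if (is.na(x$subtype)) "" else paste0(", ", x$subtype),
              nrow(x$components)))
  print(x$pooled)
  cat(sprintf("  Q = %.2f  I2 = %.0f%%\n", x$Q, 100 * x$I2))
  invisible(x)
}

#' Forest-plot data for a pooled MR result
#'
#' One row per cohort (OR, 95% CI, normalized inverse-variance weight,
#' area-proportional to which forest-plot boxes are drawn) plus a summary
#' row carrying the pooled estimate.
#'
#' @param meta An `mr_meta` from [fixed_effect_meta()].
#' @return data.frame with columns `label`, `or`, `ci_low`, `ci_high`,
#'   `weight` (NA on the summary row), `is_summary`.
#' @export
forest_data <- function(meta) {
  stopifnot(inherits(meta, "mr_meta"))
  z <- stats::qnorm(1 - meta$pooled$alpha / 2)
  comp <- meta$components
  rows <- data.frame(
    label = comp$cohort,
    or = exp(comp$beta),
    ci_low = exp(comp$beta - z * comp$se),
    ci_high = exp(comp$beta + z * comp$se),
    weight = comp$weight,
    is_summary = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(rows, data.frame(
    label = "pooled", or = meta$pooled$or, ci_low = meta$pooled$ci_low,
    ci_high = meta$pooled$ci_high, weight = NA_real_, is_summary = TRUE,
    stringsAsFactors = FALSE
  ))
}

#' Collapse a multi-cohort harmonized table to pooled per-SNP effects
#'
#' Fixed-effect meta-analysis of each SNP's outcome effect across
#' cohorts (the exposure side is shared, so `x`/`sigma_x` pass through).
#' Pleiotropic direct effects are a property of the SNP and therefore
#' identical in every cohort; tests that target them (the MR-Egger
#' intercept) must be run on these pooled effects — per-cohort intercepts
#' are not independent and pooling them understates the standard error.
#'
#' @param h Harmonized instrument data.frame spanning >= 1 cohort.
#' @return One-row-per-SNP harmonized data.frame (`cohort = "pooled"`).
#' @export
pool_snp_effects <- function(h) {
  d <- .active_instruments(h)
  rows <- lapply(split(d, d$snp_id), function(s) {
    w <- s$sigma_y^-2
    out <- s[1, , drop = FALSE]
    out$y <- sum(w * s$y) / sum(w)
    out$sigma_y <- sqrt(1 / sum(w))
    out$cohort <- "pooled"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' Run the requested estimators in every cohort of one harmonized
#' subtype slice, then pool per method.  MR-Egger defaults to a single
#' regression on cohort-pooled per-SNP effects (see
#' [pool_snp_effects()]); `egger_order = "per_cohort"` instead pools
#' per-cohort slopes and intercepts by fixed-effect meta-analysis.
estimate_by_cohort <- function(h, methods = c("IVW", "MLE"), alpha = 0.05,
                               mle_opts = list(),
                               egger_order = c("pool_snps_first", "per_cohort"),
                               egger_t = FALSE) {
  egger_order <- match.arg(egger_order)
  cohorts <- unique(h$cohort)
  per_cohort <- list(); meta <- list(); egger <- NULL
  run1 <- function(method, d) {
    switch(method,
      IVW = ivw_estimate(d, alpha),
      MLE = mle_estimate(d, alpha, opts = mle_opts),
      stop("unknown method: ", method))
  }
  for (m in setdiff(methods, "Egger")) {
    ests <- lapply(cohorts, function(cc) {
      run1(m, h[h$cohort == cc, , drop = FALSE])
    })
    names(ests) <- cohorts
    meta[[m]] <- fixed_effect_meta(ests, method = m,
                                   subtype = h$subtype[1], alpha = alpha)
    per_cohort[[m]] <- meta[[m]]$components
  }
  if ("Egger" %in% methods) {
    if (egger_order == "pool_snps_first") {
      fit <- egger_regression(pool_snp_effects(h), alpha, t_dist = egger_t)
      egger <- list(slope = fit$slope, intercept = fit$intercept,
                    order = egger_order, residual_scale = fit$residual_scale)
    } else {
      fits <- lapply(cohorts, function(cc) {
        egger_regression(h[h$cohort == cc, , drop = FALSE], alpha,
                         t_dist = egger_t)
      })
      names(fits) <- cohorts
      slope_meta <- fixed_effect_meta(lapply(fits, `[[`, "slope"),
                                      method = "Egger_slope",
                                      subtype = h$subtype[1], alpha = alpha)
      idf <- data.frame(
        cohort = cohorts,
        beta = vapply(fits, function(f) f$intercept$estimate, numeric(1)),
        se = vapply(fits, function(f) f$intercept$se, numeric(1)),
        stringsAsFactors = FALSE
      )
      w <- idf$se^-2
      a <- sum(w * idf$beta) / sum(w); sa <- sqrt(1 / sum(w))
      z <- stats::qnorm(1 - alpha / 2)
      egger <- list(
        slope = slope_meta$pooled,
        intercept = list(estimate = a, se = sa, ci_low = a - z * sa,
                         ci_high = a + z * sa,
                         p = 2 * stats::pnorm(-abs(a / sa))),
        order = egger_order, per_cohort = fits
      )
    }
  }
  list(meta = meta, per_cohort = per_cohort, egger = egger)
}
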