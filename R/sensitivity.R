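#' @keywords internal
#' Pooled (or single-cohort) estimate of one method on a harmonized
#' subset; returns NULL when the method is not estimable on the subset.
.estimate_subset <- function(h, method, alpha = 0.05) {
  run <- function(d) {
    switch(method,
      IVW = ivw_estimate(d, alpha),
      MLE = mle_estimate(d, alpha),
      Egger = egger_regression(d, alpha)$slope,
      stop("unknown method: ", method))
  }
  cohorts <- unique(h$cohort)
  tryCatch({
    if (length(cohorts) <= 1) run(h)
    else {
      ests <- lapply(cohorts, function(cc) run(h[h$cohort == cc, , drop = FALSE]))
      names(ests) <- cohorts
      fixed_effect_meta(ests, alpha = alpha)$pooled
    }
  }, error = function(e) NULL)
}

#' @keywords internal
.sensitivity_row <- function(label, snps, method, est, full_est) {
  if (is.null(est)) {
    return(data.frame(label = label, method = method,
                      n_snps = length(snps), estimable = FALSE,
                      beta = NA_real_, se = NA_real_, or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      delta_beta = NA_real_, stringsAsFactors = FALSE))
  }
  data.frame(label = label, method = method, n_snps = est$n_snps,
             estimable = TRUE, beta = est$beta, se = est$se, or = est$or,
             ci_low = est$ci_low, ci_high = est$ci_high, p = est$p,
             delta_beta = if (is.null(full_est)) NA_real_ else est$beta - full_est$beta,
             stringsAsFactors = FALSE)
}

#' Stratified MR sensitivity analysis
#'
#' Re-estimates the causal effect within strata of the instrument set —
#' here the vitamin D *synthesis* variants (rs12785878, rs10741657)
#' versus the *metabolism* variants (rs2282679, rs6013897).  Agreement
#' between strata argues against stratum-specific horizontal pleiotropy.
#' Multi-cohort inputs are estimated per cohort and pooled by
#' fixed-effect meta-analysis, exactly as the primary analysis.
#'
#' @param instruments Harmonized instrument data.frame; may span several
#'   cohorts (column `cohort`).
#' @param strata Either a named character vector mapping `snp_id` to a
#'   stratum label, or the name of a column of `instruments` (default
#'   `"pathway"`).  Every instrument must be assigned.
#' @param methods Estimators to run per stratum; `"Egger"` cells on
#'   strata with fewer than 3 SNPs are reported not estimable.
#' @param alpha CI level.
#' @return data.frame with one row per (stratum, method): `label`,
#'   `method`, `n_snps`, `estimable`, `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `delta_beta` (difference from the full-set
#'   estimate).  The full-set estimate is included with label `"all"`.
#' @export
stratified_analysis <- function(instruments, strata = "pathway",
                                methods = c("IVW", "MLE"), alpha = 0.05) {
  h <- .active_instruments(instruments)
  if (is.character(strata) && length(strata) == 1 && strata %in% names(h)) {
    assignment <- stats::setNames(h[[strata]], h$snp_id)
    assignment <- assignment[!duplicated(names(assignment))]
  } else {
    assignment <- strata
  }
  missing <- setdiff(unique(h$snp_id), names(assignment))
  if (length(missing) > 0) {
    stop("instruments without a stratum: ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (m in methods) {
    full <- .estimate_subset(h, m, alpha)
    out[[length(out) + 1]] <-
      .sensitivity_row("all", unique(h$snp_id), m, full, NULL)
    for (s in unique(assignment)) {
      snps <- names(assignment)[assignment == s]
      hs <- h[h$snp_id %in% snps, , drop = FALSE]
      if (nrow(hs) == 0) {
        warning("stratum '", s, "' contains no instruments; skipped")
        next
      }
      out[[length(out) + 1]] <-
        .sensitivity_row(s, snps, m, .estimate_subset(hs, m, alpha), full)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Instrument-exclusion sensitivity analysis
#'
#' Re-estimates the causal effect after dropping named instruments —
#' here rs12785878, whose frequency varies with ancestry, to probe
#' population-stratification bias.  Reports the change in the estimate
#' relative to the full instrument set.
#'
#' @inheritParams stratified_analysis
#' @param drop Character vector of snp_ids to exclude; must be a subset
#'   of the instrument ids and must leave at least one instrument.
#' @return data.frame as in [stratified_analysis()], with rows labelled
#'   `"all"` and `"excl:<ids>"`.
#' @export
exclusion_analysis <- function(instruments, drop,
                               methods = c("IVW", "MLE"), alpha = 0.05) {
  h <- .active_instruments(instruments)
  ids <- unique(h$snp_id)
  if (!all(drop %in% ids)) {
    stop("drop contains SNPs not in the instrument set: ",
         paste(setdiff(drop, ids), collapse = ", "))
  }
  keep <- setdiff(ids, drop)
  if (length(keep) == 0) stop("exclusion leaves no instruments")
  hr <- h[h$snp_id %in% keep, , drop = FALSE]
  label <- if (length(drop) == 0) "all" else
    paste0("excl:", paste(sort(drop), collapse = ","))
  out <- list()
  for (m in methods) {
    full <- .estimate_subset(h, m, alpha)
    out[[length(out) + 1]] <- .sensitivity_row("all", ids, m, full, NULL)
    est <- if (length(drop) == 0) full else .estimate_subset(hr, m, alpha)
    out[[length(out) + 1]] <- .sensitivity_row(label, keep, m, est, full)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
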