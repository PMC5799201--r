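#' @keywords internal
.complement <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

#' @keywords internal
.is_palindromic <- function(a1, a2) {
  s <- paste(sort(c(a1, a2)), collapse = "")
  s %in% c("AT", "CG")
}

#' Align one outcome record to an exposure record's effect allele
#'
#' Resolves the four possible orientations of the outcome association
#' relative to the exposure association: identical allele labels,
#' swapped effect/other alleles (sign flip), strand complement, and
#' strand complement plus swap.  Palindromic SNPs (A/T or C/G), for
#' which allele labels cannot distinguish strands, are resolved by
#' comparing effect-allele frequencies: both frequencies must be present
#' and fall outside the ambiguity window `0.5 +/- palindromic_freq_window`;
#' frequencies on the same side of 0.5 confirm the label-based
#' orientation, opposite sides imply the strand complement.  Otherwise
#' the pair is excluded with reason `"palindromic_ambiguous"`.
#'
#' @param exp One-row data.frame with `snp_id`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure` and optionally `eaf`.
#' @param out One-row data.frame with `snp_id`, `effect_allele`,
#'   `other_allele`, `beta_outcome`, `se_outcome` and optionally `eaf`.
#' @param palindromic_freq_window Half-width of the frequency window
#'   around 0.5 inside which a palindromic SNP is declared ambiguous.
#'   Default 0.08, conventional in summary-data MR.
#' @param palindromic Policy for palindromic SNPs: `"freq"` (resolve by
#'   frequency as above), `"keep"` (trust that both tables are on the
#'   same strand and use label matching only), or `"exclude"`.
#' @return One-row data.frame with columns `snp_id`, `x`, `sigma_x`, `y`,
#'   `sigma_y`, `eaf_exposure`, `eaf_outcome`, `action` (one of
#'   `kept_as_is`, `sign_flipped`, `strand_flipped`, `excluded`),
#'   `sign_change` (logical) and `exclusion_reason`.
#' @export
harmonize_pair <- function(exp, out, palindromic_freq_window = 0.08,
                           palindromic = c("freq", "keep", "exclude")) {
  palindromic <- match.arg(palindromic)
  if (exp$snp_id != out$snp_id) {
    stop("harmonize_pair: snp_id mismatch: ", exp$snp_id, " vs ", out$snp_id)
  }
  e_ea <- toupper(exp$effect_allele); e_oa <- toupper(exp$other_allele)
  o_ea <- toupper(out$effect_allele); o_oa <- toupper(out$other_allele)
  eaf_e <- if ("eaf" %in% names(exp)) exp$eaf else NA_real_
  eaf_o <- if ("eaf" %in% names(out)) out$eaf else NA_real_

  res <- function(action, y, sign_change, reason = NA_character_) {
    data.frame(
      snp_id = exp$snp_id,
      x = exp$beta_exposure, sigma_x = exp$se_exposure,
      y = y, sigma_y = out$se_outcome,
      eaf_exposure = eaf_e, eaf_outcome = eaf_o,
      action = action, sign_change = sign_change,
      exclusion_reason = reason, stringsAsFactors = FALSE
    )
  }
  excl <- function(reason) res("excluded", NA_real_, FALSE, reason)

  pal <- .is_palindromic(e_ea, e_oa)

  # label-based orientation (strand taken at face value)
  if (o_ea == e_ea && o_oa == e_oa) {
    base_action <- "kept_as_is"; y <- out$beta_outcome
    eaf_aligned <- eaf_o; sign_change <- FALSE
  } else if (o_ea == e_oa && o_oa == e_ea) {
    base_action <- "sign_flipped"; y <- -out$beta_outcome
    eaf_aligned <- 1 - eaf_o; sign_change <- TRUE
  } else if (!pal && .complement(o_ea) == e_ea && .complement(o_oa) == e_oa) {
    base_action <- "strand_flipped"; y <- out$beta_outcome
    eaf_aligned <- eaf_o; sign_change <- FALSE
  } else if (!pal && .complement(o_ea) == e_oa && .complement(o_oa) == e_ea) {
    base_action <- "strand_flipped"; y <- -out$beta_outcome
    eaf_aligned <- 1 - eaf_o; sign_change <- TRUE
  } else {
    return(excl("allele_mismatch"))
  }

  if (pal) {
    if (palindromic == "exclude") return(excl("palindromic_excluded"))
    if (palindromic == "freq") {
      w <- palindromic_freq_window
      informative <- function(f) !is.na(f) && (f < 0.5 - w || f > 0.5 + w)
      if (!informative(eaf_e) || !informative(eaf_aligned)) {
        return(excl("palindromic_ambiguous"))
      }
      same_side <- (eaf_e < 0.5) == (eaf_aligned < 0.5)
      if (!same_side) {
        # true orientation is the strand complement of the label match
        y <- -y
        sign_change <- !sign_change
        base_action <- "strand_flipped"
      }
    }
    # palindromic == "keep": accept the label-based orientation as-is
  }
  res(base_action, y, sign_change)
}

#' Harmonize an exposure table against a multi-cohort outcome table
#'
#' Applies [harmonize_pair()] to every (SNP, cohort, subtype) combination
#' present in `outcome` for SNPs present in `exposure`.  Nothing is
#' dropped silently: every pair appears in the result with its `action`,
#' and excluded pairs carry a machine-readable `exclusion_reason`.
#'
#' @param exposure Exposure association table (see
#'   [builtin_sunlight_instruments()] for the layout).
#' @param outcome Outcome association table with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_outcome`, `se_outcome`,
#'   `cohort`, `subtype` and optionally `eaf`.
#' @inheritParams harmonize_pair
#' @return A data.frame, one row per (SNP, cohort, subtype) pair, with the
#'   [harmonize_pair()] columns plus `cohort`, `subtype` and, when present
#'   in `exposure`, `pathway`.
#' @export
harmonize_dataset <- function(exposure, outcome,
                              palindromic_freq_window = 0.08,
                              palindromic = c("freq", "keep", "exclude")) {
  palindromic <- match.arg(palindromic)
  stopifnot(nrow(exposure) > 0, nrow(outcome) > 0)
  outcome <- outcome[outcome$snp_id %in% exposure$snp_id, , drop = FALSE]
  if (nrow(outcome) == 0) stop("no outcome records match the instrument set")
  rows <- lapply(seq_len(nrow(outcome)), function(i) {
    o <- outcome[i, , drop = FALSE]
    e <- exposure[exposure$snp_id == o$snp_id, , drop = FALSE][1, , drop = FALSE]
    h <- harmonize_pair(e, o, palindromic_freq_window, palindromic)
    h$cohort <- o$cohort
    h$subtype <- o$subtype
    if ("pathway" %in% names(e)) h$pathway <- e$pathway
    h
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_excl <- sum(out$action == "excluded")
  if (n_excl > 0) {
    warning(n_excl, " instrument pair(s) excluded during harmonization (",
            paste(unique(out$exclusion_reason[out$action == "excluded"]),
                  collapse = ", "), ")")
  }
  out
}

#' Orient harmonized instruments to the increasing-exposure scale
#'
#' The built-in instrument set is coded on the 25(OH)D-*decreasing*
#' allele, so all exposure effects are negative.  Estimators are
#' invariant to jointly negating (x, y), so for presentation the pipeline
#' reports effects per unit *increase* in 25(OH)D (odds ratio < 1 means
#' higher vitamin D is protective).  This flips (x, y) jointly wherever
#' x < 0; it never changes an estimate.
#'
#' @param h A harmonized instrument data.frame.
#' @return The same data.frame with (x, y) jointly negated where x < 0.
#' @export
orient_to_increasing <- function(h) {
  flip <- !is.na(h$x) & h$x < 0
  h$x[flip] <- -h$x[flip]
  h$y[flip] <- -h$y[flip]
  h
}

#' Pairwise linkage-disequilibrium independence check
#'
#' Instruments must be mutually independent (pairwise r^2 below a small
#' threshold) for their ratio estimates to be combined as if independent.
#' The check runs against a user-supplied precomputed r^2 matrix; with no
#' matrix every pair is reported `"unchecked"` with a warning, since LD
#' cannot be inferred from summary statistics alone.
#'
#' @param snp_ids Character vector of instrument SNP ids (>= 2).
#' @param r2_matrix Symmetric matrix of pairwise r^2 with dimnames
#'   covering `snp_ids`, or `NULL`.
#' @param threshold Pairs with r^2 >= `threshold` are flagged dependent.
#'   Default 0.001, the independence cutoff asserted for this instrument
#'   set.
#' @return data.frame with columns `snp_a`, `snp_b`, `r2` (NA when
#'   unchecked), `independent` (logical, NA when unchecked), `status`
#'   (`"checked"`/`"unchecked"`).
#' @export
check_ld_independence <- function(snp_ids, r2_matrix = NULL,
                                  threshold = 0.001) {
  stopifnot(length(snp_ids) >= 2)
  prs <- utils::combn(snp_ids, 2)
  if (is.null(r2_matrix)) {
    warning("no LD matrix supplied; pairwise independence unchecked")
    return(data.frame(
      snp_a = prs[1, ], snp_b = prs[2, ], r2 = NA_real_,
      independent = NA, status = "unchecked", stringsAsFactors = FALSE
    ))
  }
  if (!isSymmetric(unname(r2_matrix))) {
    stop("r2_matrix must be symmetric")
  }
  if (!all(snp_ids %in% rownames(r2_matrix))) {
    stop("r2_matrix does not cover all snp_ids")
  }
  r2 <- mapply(function(a, b) r2_matrix[a, b], prs[1, ], prs[2, ])
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  data.frame(
    snp_a = prs[1, ], snp_b = prs[2, ], r2 = unname(r2),
    independent = unname(r2) < threshold, status = "checked",
    stringsAsFactors = FALSE
  )
}

#' Single-SNP F-statistic from effect and standard error
#'
#' For a single variant the instrument-strength F-statistic is the
#' squared Wald ratio (beta/se)^2.
#'
#' @param beta Per-allele effect estimate.
#' @param se Its standard error (> 0).
#' @return (beta/se)^2, vectorised.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

#' Standard error recovered from an F-statistic
#'
#' Inverts [f_statistic()]: se = |beta| / sqrt(F).  This is how the
#' exposure-side standard errors of the built-in instrument set were
#' derived from previously reported F-statistics.
#'
#' @param beta Per-allele effect estimate.
#' @param f Single-SNP F-statistic (> 0).
#' @return |beta| / sqrt(f), vectorised.
#' @export
se_from_f <- function(beta, f) {
  if (any(f <= 0)) stop("f must be > 0")
  abs(beta) / sqrt(f)
}
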