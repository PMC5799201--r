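#' Configuration for a synthetic two-sample MR dataset
#'
#' Describes a multi-cohort summary-level dataset generated under the
#' same bivariate-normal model the estimators assume: true per-SNP
#' exposure effects xi_k, observed exposure effects
#' `x_k ~ N(xi_k, sigma_x_k^2)`, and per-cohort outcome log-ORs
#' `y_kc ~ N(beta * xi_k + alpha_k, sigma_y_kc^2)`, where alpha_k is a
#' per-SNP direct (pleiotropic) effect shared across cohorts.  Outcome
#' SEs follow the standard binary-trait GWAS approximation
#' `sigma_y = 1 / sqrt(2 f (1-f) N K (1-K))` (f the effect-allele
#' frequency, N the cohort size, K its case fraction), which makes the
#' per-SNP signal-to-noise weak — O(1) — at realistic glioma sample
#' sizes.  Generation is at the summary level throughout; no
#' individual-level genotypes are simulated.
#'
#' @param n_snps Number of instruments.
#' @param true_beta Causal log-OR per unit of the exposure scale.
#' @param xi_range Interval from which true exposure effects are drawn
#'   uniformly (negative by default: decreasing-allele orientation, as in
#'   the built-in instrument set).  Ignored when `xi_fixed` is given.
#' @param sigma_x_range Interval for exposure-side SEs; ignored when
#'   `sigma_x_fixed` is given.
#' @param xi_fixed,sigma_x_fixed,eaf_fixed Optional fixed vectors
#'   (length `n_snps`) overriding the random draws.
#' @param cohorts data.frame with columns `label`, `n_cases`,
#'   `n_controls`.
#' @param pleiotropy List `type` (`"none"`, `"balanced"`,
#'   `"directional"`), `mean`, `sd` of the per-SNP direct effects.
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G
#'   alleles.
#' @param subtype Outcome subtype label stamped on the outcome table.
#' @param seed RNG seed; the dataset is fully reproducible given it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 4,
                              true_beta = 0,
                              xi_range = c(-0.06, -0.025),
                              sigma_x_range = c(0.012, 0.015),
                              xi_fixed = NULL,
                              sigma_x_fixed = NULL,
                              eaf_fixed = NULL,
                              cohorts = NULL,
                              pleiotropy = list(type = "none", mean = 0, sd = 0),
                              palindromic_fraction = 0.25,
                              subtype = "all_glioma",
                              seed = 1L) {
  if (is.null(cohorts)) cohorts <- .default_cohorts()
  cfg <- structure(
    list(n_snps = n_snps, true_beta = true_beta, xi_range = xi_range,
         sigma_x_range = sigma_x_range, xi_fixed = xi_fixed,
         sigma_x_fixed = sigma_x_fixed, eaf_fixed = eaf_fixed,
         cohorts = cohorts, pleiotropy = pleiotropy,
         palindromic_fraction = palindromic_fraction,
         subtype = subtype, seed = as.integer(seed)),
    class = "simulation_config")
  .validate_sim_config(cfg)
  cfg
}

#' @keywords internal
.default_cohorts <- function() {
  # 12,488 cases / 18,169 controls split evenly over the eight cohorts
  # (per-cohort counts are not published); 18,169 = 8 * 2271 + 1
  data.frame(
    label = .paper_cohorts,
    n_cases = rep(1561L, 8),
    n_controls = c(rep(2271L, 7), 2272L),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
.validate_sim_config <- function(cfg) {
  if (cfg$n_snps < 1) stop("config error: n_snps must be >= 1")
  chk_range <- function(r, name, positive = FALSE) {
    if (length(r) != 2 || r[1] > r[2]) {
      stop("config error: ", name, " must be an ordered interval")
    }
    if (positive && r[1] <= 0) stop("config error: ", name, " must be positive")
  }
  if (is.null(cfg$xi_fixed)) chk_range(cfg$xi_range, "xi_range")
  if (is.null(cfg$sigma_x_fixed)) chk_range(cfg$sigma_x_range, "sigma_x_range", TRUE)
  for (nm in c("xi_fixed", "sigma_x_fixed", "eaf_fixed")) {
    v <- cfg[[nm]]
    if (!is.null(v) && length(v) != cfg$n_snps) {
      stop("config error: ", nm, " must have length n_snps")
    }
  }
  if (!is.null(cfg$sigma_x_fixed) && any(cfg$sigma_x_fixed <= 0)) {
    stop("config error: sigma_x_fixed must be positive")
  }
  if (cfg$palindromic_fraction < 0 || cfg$palindromic_fraction > 1) {
    stop("config error: palindromic_fraction must be in [0, 1]")
  }
  if (!cfg$pleiotropy$type %in% c("none", "balanced", "directional")) {
    stop("config error: unknown pleiotropy type: ", cfg$pleiotropy$type)
  }
  if (any(cfg$cohorts$n_cases <= 0) || any(cfg$cohorts$n_controls <= 0)) {
    stop("config error: cohort counts must be positive")
  }
  invisible(cfg)
}

#' Scenario presets for simulation studies
#'
#' * `"paper_like"` — the four real instruments (their exposure effects,
#'   SEs, alleles and realistic European effect-allele frequencies
#'   0.28/0.40/0.23/0.21), eight cohorts totalling 12,488 cases and
#'   18,169 controls, causal effect log(0.62) (the GBM-scale protective
#'   effect), no pleiotropy.  The rs12785878 outcome record is emitted
#'   with swapped alleles, as in the source glioma meta-analysis, so the
#'   pipeline's sign-flip harmonization is exercised.
#' * `"null"` — paper_like with `true_beta = 0`.
#' * `"causal"` — paper_like (alias kept for symmetry).
#' * `"balanced_pleiotropy"` — null plus per-SNP direct effects
#'   `alpha_k ~ N(0, 0.05)`.
#' * `"directional_pleiotropy"` — null plus `alpha_k ~ N(0.05, 0.02)`.
#'
#' @param name Scenario name.
#' @param seed Seed stored in the returned config.
#' @return A [simulation_config()].
#' @export
scenario_presets <- function(name = c("null", "causal", "balanced_pleiotropy",
                                      "directional_pleiotropy", "paper_like"),
                             seed = 1L) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("null", "causal", "balanced_pleiotropy",
                   "directional_pleiotropy", "paper_like")) {
    stop("unknown scenario name: ", if (is.character(name)) name[1] else "<non-string>")
  }
  instr <- builtin_sunlight_instruments()
  base <- simulation_config(
    n_snps = 4,
    true_beta = log(0.62),
    xi_fixed = instr$beta_exposure,
    sigma_x_fixed = instr$se_exposure,
    eaf_fixed = c(0.28, 0.40, 0.23, 0.21),
    palindromic_fraction = 0.25,
    seed = seed
  )
  switch(name,
    paper_like = base,
    causal = base,
    null = { base$true_beta <- 0; base },
    balanced_pleiotropy = {
      base$true_beta <- 0
      base$pleiotropy <- list(type = "balanced", mean = 0, sd = 0.05)
      base
    },
    directional_pleiotropy = {
      base$true_beta <- 0
      base$pleiotropy <- list(type = "directional", mean = 0.05, sd = 0.02)
      base
    })
}

#' @keywords internal
.sim_alleles <- function(n, palindromic_fraction) {
  n_pal <- round(palindromic_fraction * n)
  pal_idx <- if (n_pal > 0) sample(n, n_pal) else integer(0)
  pal_pairs <- list(c("A", "T"), c("C", "G"))
  nonpal <- list(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"),
                 c("G", "A"), c("T", "C"))
  ea <- character(n); oa <- character(n)
  for (i in seq_len(n)) {
    p <- if (i %in% pal_idx) pal_pairs[[sample(2, 1)]] else nonpal[[sample(6, 1)]]
    ea[i] <- p[1]; oa[i] <- p[2]
  }
  list(ea = ea, oa = oa, palindromic = seq_len(n) %in% pal_idx)
}

#' Generate one synthetic multi-cohort summary dataset
#'
#' Draws a dataset under the model described in [simulation_config()].
#' Whether each SNP's outcome record is emitted with swapped
#' effect/other alleles (requiring a harmonization sign flip) is part of
#' the reproducible draw; outcome effect-allele frequencies get small
#' sampling noise (SD 0.01).  The truth record carries everything needed
#' to score any estimator.
#'
#' @param config A [simulation_config()].
#' @return List of class `simulated_dataset`: `exposure` (one row per
#'   SNP, layout of [builtin_sunlight_instruments()] minus metadata),
#'   `outcome` (one row per SNP x cohort), and `truth`
#'   (`true_beta`, `xi`, `alpha_k`, `eaf`, `swapped`).
#' @export
simulate_dataset <- function(config) {
  .validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_snps
  xi <- if (!is.null(config$xi_fixed)) config$xi_fixed else
    stats::runif(n, config$xi_range[1], config$xi_range[2])
  sx <- if (!is.null(config$sigma_x_fixed)) config$sigma_x_fixed else
    stats::runif(n, config$sigma_x_range[1], config$sigma_x_range[2])
  eaf <- if (!is.null(config$eaf_fixed)) config$eaf_fixed else
    stats::runif(n, 0.10, 0.40)
  x_obs <- stats::rnorm(n, xi, sx)

  pl <- config$pleiotropy
  alpha_k <- switch(pl$type,
    none = rep(0, n),
    balanced = stats::rnorm(n, 0, pl$sd),
    directional = stats::rnorm(n, pl$mean, pl$sd))

  paper_like <- !is.null(config$xi_fixed) && n == 4 &&
    isTRUE(all.equal(config$xi_fixed, builtin_sunlight_instruments()$beta_exposure))
  if (paper_like) {
    instr <- builtin_sunlight_instruments()
    snp_id <- instr$snp_id; ea <- instr$effect_allele; oa <- instr$other_allele
    out_ea <- instr$glioma_ea; out_oa <- instr$glioma_nea
    swapped <- out_ea != ea
  } else {
    snp_id <- sprintf("rs%07d", sample(1e6, n))
    al <- .sim_alleles(n, config$palindromic_fraction)
    ea <- al$ea; oa <- al$oa
    swapped <- stats::runif(n) < 0.5
    # palindromic SNPs keep the exposure orientation so that frequency
    # resolution, not label matching, is what the harmonizer must rely on
    swapped[al$palindromic] <- FALSE
    out_ea <- ifelse(swapped, oa, ea)
    out_oa <- ifelse(swapped, ea, oa)
  }

  exposure <- data.frame(
    snp_id = snp_id, chrom = NA_character_, position = NA_integer_,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta_exposure = x_obs, se_exposure = sx,
    f_stat = (x_obs / sx)^2,
    locus = NA_character_,
    pathway = if (paper_like) builtin_sunlight_instruments()$pathway
              else rep("unknown", n),
    stringsAsFactors = FALSE
  )

  ch <- config$cohorts
  out_rows <- vector("list", nrow(ch))
  for (ci in seq_len(nrow(ch))) {
    nn <- ch$n_cases[ci] + ch$n_controls[ci]
    kk <- ch$n_cases[ci] / nn
    sy <- 1 / sqrt(2 * eaf * (1 - eaf) * nn * kk * (1 - kk))
    y_aligned <- stats::rnorm(n, config$true_beta * xi + alpha_k, sy)
    eaf_out <- pmin(pmax(eaf + stats::rnorm(n, 0, 0.01), 0.01), 0.99)
    out_rows[[ci]] <- data.frame(
      snp_id = snp_id,
      effect_allele = out_ea, other_allele = out_oa,
      eaf = ifelse(swapped, 1 - eaf_out, eaf_out),
      beta_outcome = ifelse(swapped, -y_aligned, y_aligned),
      se_outcome = sy,
      cohort = ch$label[ci], subtype = config$subtype,
      stringsAsFactors = FALSE
    )
  }
  outcome <- do.call(rbind, out_rows)
  rownames(outcome) <- NULL

  structure(list(
    exposure = exposure, outcome = outcome,
    truth = list(true_beta = config$true_beta, xi = xi, alpha_k = alpha_k,
                 eaf = eaf, swapped = swapped)
  ), class = "simulated_dataset")
}

#' Monte-Carlo study over replicated synthetic datasets
#'
#' Repeatedly simulates a scenario, runs the full analysis chain
#' (harmonize, orient to the increasing-exposure scale, estimate per
#' cohort, pool by fixed-effect meta-analysis) and collects the pooled
#' estimates.  Replicate r uses seed `seed + r`, so the study is
#' reproducible and replicates are independent.
#'
#' @param config A [simulation_config()] (its `seed` is overridden per
#'   replicate).
#' @param n_reps Number of replicates.
#' @param methods Estimators: subset of `"IVW"`, `"MLE"`, `"Egger"`.
#' @param alpha CI level.
#' @param seed Base seed.
#' @param io_roundtrip If `TRUE`, each replicate's tables are written to
#'   disk and read back before analysis (slower; verifies the IO layer
#'   inside the loop).
#' @param egger_order,egger_t Passed through to the Egger stage (see
#'   [pool_snp_effects()] and [egger_regression()]).
#' @return data.frame with one row per (replicate, method): `rep`,
#'   `method`, `beta`, `se`, `p`, plus `egger_intercept`,
#'   `egger_intercept_p` on Egger rows.  Attribute `true_beta` holds the
#'   generating causal effect (the slope is invariant to the
#'   presentation orientation, so no sign change applies).
#' @export
mr_mc_study <- function(config, n_reps, methods = c("IVW", "MLE"),
                        alpha = 0.05, seed = 1L, io_roundtrip = FALSE,
                        egger_order = "pool_snps_first", egger_t = FALSE) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config; cfg$seed <- as.integer(seed + r)
    ds <- simulate_dataset(cfg)
    exposure <- ds$exposure; outcome <- ds$outcome
    if (io_roundtrip) {
      td <- tempfile("mrmc"); dir.create(td)
      on.exit(unlink(td, recursive = TRUE), add = TRUE)
      ep <- file.path(td, "exp.tsv"); op <- file.path(td, "out.tsv")
      utils::write.table(exposure, ep, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(outcome, op, sep = "\t", quote = FALSE, row.names = FALSE)
      exposure <- read_exposure_table(ep)
      outcome <- read_outcome_table(op)
    }
    h <- suppressWarnings(harmonize_dataset(exposure, outcome))
    h <- orient_to_increasing(h)
    fit <- estimate_by_cohort(h, methods = methods, alpha = alpha,
                              egger_order = egger_order, egger_t = egger_t)
    rr <- list()
    for (m in setdiff(methods, "Egger")) {
      p <- fit$meta[[m]]$pooled
      rr[[m]] <- data.frame(rep = r, method = m, beta = p$beta, se = p$se,
                            p = p$p, egger_intercept = NA_real_,
                            egger_intercept_p = NA_real_)
    }
    if ("Egger" %in% methods) {
      s <- fit$egger$slope
      rr$Egger <- data.frame(rep = r, method = "Egger", beta = s$beta,
                             se = s$se, p = s$p,
                             egger_intercept = fit$egger$intercept$estimate,
                             egger_intercept_p = fit$egger$intercept$p)
    }
    rows[[r]] <- do.call(rbind, rr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_beta") <- config$true_beta
  out
}

#' Score estimator performance against the simulation truth
#'
#' @param truth Either a `truth` record from [simulate_dataset()], a
#'   number (the true causal effect on the reported scale), or omitted
#'   to use the `true_beta` attribute of `estimates`.
#' @param estimates Output of [mr_mc_study()] (or any data.frame with
#'   `method`, `beta`, `se`, `p`).
#' @param alpha Nominal level used for coverage and rejection.
#' @return data.frame, one row per method: `method`, `n_reps`, `bias`,
#'   `rmse`, `coverage` (95% CI covers the truth), `rejection_rate`
#'   (p < alpha; type-I error under a null truth, power otherwise).
#' @export
score_estimates <- function(truth = NULL, estimates, alpha = 0.05) {
  tb <- if (is.null(truth)) attr(estimates, "true_beta")
        else if (is.list(truth)) truth$true_beta else truth
  if (is.null(tb)) stop("no truth available to score against")
  z <- stats::qnorm(1 - alpha / 2)
  out <- lapply(split(estimates, estimates$method), function(d) {
    err <- d$beta - tb
    data.frame(
      method = d$method[1], n_reps = nrow(d),
      bias = mean(err), rmse = sqrt(mean(err^2)),
      coverage = mean(d$beta - z * d$se <= tb & tb <= d$beta + z * d$se),
      rejection_rate = mean(d$p < alpha),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
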