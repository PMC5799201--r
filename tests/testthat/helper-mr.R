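# Builders for harmonized instrument tables and independent oracles.

make_h <- function(x, y, sigma_y, sigma_x = rep(1e-3, length(x)),
                   cohort = "C1", subtype = "all_glioma",
                   snp_id = paste0("rs", seq_along(x))) {
  data.frame(
    snp_id = snp_id, x = x, sigma_x = sigma_x, y = y, sigma_y = sigma_y,
    eaf_exposure = NA_real_, eaf_outcome = NA_real_,
    action = "kept_as_is", sign_change = FALSE,
    exclusion_reason = NA_character_,
    cohort = cohort, subtype = subtype, stringsAsFactors = FALSE
  )
}

random_h <- function(k, seed) {
  set.seed(seed)
  make_h(
    x = runif(k, 0.02, 0.08) * sample(c(-1, 1), k, replace = TRUE),
    y = rnorm(k, 0, 0.05),
    sigma_y = runif(k, 0.02, 0.08),
    sigma_x = runif(k, 0.005, 0.02)
  )
}

# Weighted regression through the origin via lm(): independent IVW oracle.
ivw_oracle <- function(h) {
  f <- lm(y ~ 0 + x, data = h, weights = h$sigma_y^-2)
  s <- summary(f)
  list(beta = unname(coef(f)["x"]),
       se = sqrt(s$cov.unscaled["x", "x"]))
}

# Weighted regression with intercept via lm(): independent Egger oracle
# (SEs rebuilt from the unscaled covariance with the max(1, sigma) floor).
egger_oracle <- function(h) {
  flip <- h$x < 0
  d <- h
  d$x[flip] <- -d$x[flip]; d$y[flip] <- -d$y[flip]
  f <- lm(y ~ x, data = d, weights = d$sigma_y^-2)
  s <- summary(f)
  scale <- max(1, s$sigma)
  list(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]),
       se_intercept = sqrt(s$cov.unscaled[1, 1]) * scale,
       se_slope = sqrt(s$cov.unscaled[2, 2]) * scale)
}

make_exposure <- function(snp_id, ea, oa, beta, se, eaf = NA_real_,
                          pathway = "unknown") {
  data.frame(snp_id = snp_id, chrom = NA_character_, position = NA_integer_,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta_exposure = beta, se_exposure = se,
             f_stat = (beta / se)^2, locus = NA_character_,
             pathway = pathway, stringsAsFactors = FALSE)
}

make_outcome <- function(snp_id, ea, oa, beta, se, eaf = NA_real_,
                         cohort = "C1", subtype = "all_glioma") {
  data.frame(snp_id = snp_id, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta_outcome = beta, se_outcome = se,
             cohort = cohort, subtype = subtype, stringsAsFactors = FALSE)
}
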