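test_that("allele orientation cases resolve as documented", {
  e <- make_exposure("rs1", "G", "T", -0.05, 0.01)

  # identical labels: kept as-is
  h <- harmonize_pair(e, make_outcome("rs1", "G", "T", 0.02, 0.05))
  expect_equal(h$action, "kept_as_is")
  expect_equal(h$y, 0.02)

  # swapped labels: sign flip
  e2 <- make_exposure("rs1", "G", "A", -0.05, 0.01)
  h <- harmonize_pair(e2, make_outcome("rs1", "A", "G", 0.02, 0.05))
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$y, -0.02)

  # strand complement: C/A reported for a G/T exposure record
  h <- harmonize_pair(e, make_outcome("rs1", "C", "A", 0.02, 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$y, 0.02)
  expect_false(h$sign_change)

  # strand complement with swap: sign flips too
  h <- harmonize_pair(e, make_outcome("rs1", "A", "C", 0.02, 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$y, -0.02)
  expect_true(h$sign_change)

  # irreconcilable alleles
  h <- harmonize_pair(e, make_outcome("rs1", "A", "G", 0.02, 0.05))
  expect_equal(h$action, "excluded")
  expect_equal(h$exclusion_reason, "allele_mismatch")

  expect_error(harmonize_pair(e, make_outcome("rs2", "G", "T", 0.02, 0.05)),
               "snp_id mismatch")
})

test_that("palindromic SNPs resolve by frequency concordance or are excluded", {
  e <- make_exposure("rs6013897", "A", "T", -0.027, 0.015, eaf = 0.20)

  # both frequencies informative and on the same side of 0.5: kept
  h <- harmonize_pair(e, make_outcome("rs6013897", "A", "T", 0.02, 0.05,
                                      eaf = 0.21),
                      palindromic_freq_window = 0.08)
  expect_equal(h$action, "kept_as_is")
  expect_equal(h$y, 0.02)

  # opposite sides of 0.5: the outcome is on the other strand
  h <- harmonize_pair(e, make_outcome("rs6013897", "A", "T", 0.02, 0.05,
                                      eaf = 0.79))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$y, -0.02)

  # swapped labels with concordant aligned frequency: plain sign flip
  h <- harmonize_pair(e, make_outcome("rs6013897", "T", "A", 0.02, 0.05,
                                      eaf = 0.80))
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$y, -0.02)

  # frequency inside the ambiguity window: excluded
  h <- harmonize_pair(e, make_outcome("rs6013897", "A", "T", 0.02, 0.05,
                                      eaf = 0.47))
  expect_equal(h$action, "excluded")
  expect_equal(h$exclusion_reason, "palindromic_ambiguous")

  # missing frequency: excluded under "freq", kept under "keep"
  out_na <- make_outcome("rs6013897", "A", "T", 0.02, 0.05)
  expect_equal(harmonize_pair(e, out_na)$action, "excluded")
  expect_equal(harmonize_pair(e, out_na, palindromic = "keep")$action,
               "kept_as_is")
  expect_equal(harmonize_pair(e, out_na, palindromic = "exclude")$exclusion_reason,
               "palindromic_excluded")
})

test_that("harmonizing an aligned pair is a no-op and swaps only flip the sign", {
  set.seed(42)
  for (i in 1:20) {
    pair <- sample(c("A", "C", "G", "T"), 2)
    if (vitdmr:::.is_palindromic(pair[1], pair[2])) next
    e <- make_exposure("rs1", pair[1], pair[2], rnorm(1, 0, 0.05), 0.01)
    y <- rnorm(1, 0, 0.05)
    o1 <- make_outcome("rs1", pair[1], pair[2], y, 0.05)
    h1 <- harmonize_pair(e, o1)
    expect_equal(h1$y, y)
    expect_equal(h1$x, e$beta_exposure)
    o2 <- make_outcome("rs1", pair[2], pair[1], y, 0.05)
    h2 <- harmonize_pair(e, o2)
    expect_equal(h2$y, -y)
    expect_equal(h2[, c("x", "sigma_x", "sigma_y")],
                 h1[, c("x", "sigma_x", "sigma_y")])
  }
})

test_that("dataset harmonization records every pair and the fixture stays negative", {
  sim <- simulate_dataset(scenario_presets("paper_like", seed = 5))
  h <- harmonize_dataset(sim$exposure, sim$outcome)
  expect_equal(nrow(h), nrow(sim$outcome))
  expect_true(all(h$action != "excluded"))
  # decreasing-allele orientation preserved for the real instruments
  expect_true(all(h$x < 0))
  # rs12785878 arrives in the swapped glioma orientation: sign flip
  expect_true(all(h$action[h$snp_id == "rs12785878"] == "sign_flipped"))
  # orientation flip is presentation only
  ho <- orient_to_increasing(h)
  expect_true(all(ho$x > 0))
  one <- h[h$cohort == h$cohort[1], ]
  expect_equal(ivw_estimate(orient_to_increasing(one))$beta,
               ivw_estimate(one)$beta)
})

test_that("LD independence check flags dependent pairs and unchecked matrices", {
  ids <- paste0("rs", 1:4)
  m <- diag(4); dimnames(m) <- list(ids, ids)
  res <- check_ld_independence(ids, m, threshold = 0.001)
  expect_equal(nrow(res), 6)  # C(4,2)
  expect_true(all(res$independent))

  m2 <- m; m2["rs1", "rs2"] <- m2["rs2", "rs1"] <- 0.5
  res <- check_ld_independence(ids, m2)
  expect_false(res$independent[res$snp_a == "rs1" & res$snp_b == "rs2"])

  expect_warning(res <- check_ld_independence(ids, NULL), "unchecked")
  expect_equal(nrow(res), 6)
  expect_true(all(res$status == "unchecked"))

  m3 <- m; m3[1, 2] <- 0.5
  expect_error(check_ld_independence(ids, m3), "symmetric")
})

test_that("F-statistic and SE recovery are exact mutual inverses", {
  expect_equal(f_statistic(-0.052, 0.012), 18.78, tolerance = 5e-4)
  expect_equal(f_statistic(0.02, 0.02), 1.0)
  expect_equal(f_statistic(0, 0.01), 0.0)
  expect_equal(round(se_from_f(-0.047, 13.38), 3), 0.013)
  expect_equal(round(se_from_f(-0.027, 3.13), 3), 0.015)
  expect_error(f_statistic(0.1, 0), "se must be")
  expect_error(se_from_f(0.1, -1), "f must be")

  set.seed(7)
  beta <- rnorm(50, 0, 0.1); se <- runif(50, 1e-4, 0.1)
  expect_equal(se_from_f(beta, f_statistic(beta, se)), se)
  expect_equal(se_from_f(beta, beta^2 * 1e6), rep(1e-3, 50))
})
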