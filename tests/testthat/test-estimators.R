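test_that("IVW matches the closed form and its single-SNP Wald limit", {
  h <- make_h(x = c(0.5, 0.25), y = c(0.1, 0.06), sigma_y = c(0.05, 0.05))
  est <- ivw_estimate(h)
  expect_equal(est$beta, 0.208, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(est$n_snps, 2)
  expect_equal(est$or, exp(est$beta))

  # all-null outcomes
  h0 <- make_h(x = c(0.5, 0.25), y = c(0, 0), sigma_y = c(0.05, 0.05))
  est0 <- ivw_estimate(h0)
  expect_equal(est0$beta, 0)
  expect_equal(est0$or, 1.0)
  expect_equal(est0$p, 1.0)

  # k = 1 reduces to the Wald ratio
  h1 <- make_h(x = 0.4, y = 0.1, sigma_y = 0.03)
  est1 <- ivw_estimate(h1)
  expect_equal(est1$beta, 0.1 / 0.4)
  expect_equal(est1$se, 0.03 / 0.4)

  expect_error(ivw_estimate(make_h(numeric(0), numeric(0), numeric(0))))
  expect_error(ivw_estimate(make_h(c(0, 0), c(0.1, 0.2), c(0.05, 0.05))),
               "degenerate")
})

test_that("IVW and Egger agree with independent weighted-lm oracles", {
  for (seed in 1:25) {
    h <- random_h(k = sample(4:12, 1), seed = seed)
    est <- ivw_estimate(h)
    orc <- ivw_oracle(h)
    expect_equal(est$beta, orc$beta, tolerance = 1e-10)
    expect_equal(est$se, orc$se, tolerance = 1e-10)

    eg <- egger_regression(h)
    eo <- egger_oracle(h)
    expect_equal(eg$slope$beta, eo$slope, tolerance = 1e-10)
    expect_equal(eg$intercept$estimate, eo$intercept, tolerance = 1e-10)
    expect_equal(eg$slope$se, eo$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept$se, eo$se_intercept, tolerance = 1e-10)
  }
})

test_that("Egger recovers exact fits and absorbs a constant offset", {
  h <- make_h(x = c(0.1, 0.2, 0.3), y = 0.2 * c(0.1, 0.2, 0.3),
              sigma_y = rep(0.05, 3))
  eg <- egger_regression(h)
  expect_equal(eg$slope$beta, 0.2, tolerance = 1e-12)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-12)

  h$y <- h$y + 0.01
  eg <- egger_regression(h)
  expect_equal(eg$slope$beta, 0.2, tolerance = 1e-12)
  expect_equal(eg$intercept$estimate, 0.01, tolerance = 1e-12)

  expect_error(egger_regression(h[1:2, ]), "at least 3")
  hc <- make_h(x = rep(0.1, 4), y = rnorm(4), sigma_y = rep(0.05, 4))
  expect_error(egger_regression(hc), "collinear")
})

test_that("MLE collapses to IVW as exposure error vanishes", {
  h <- make_h(x = c(0.5, 0.25), y = c(0.1, 0.06), sigma_y = c(0.05, 0.05),
              sigma_x = c(1e-8, 1e-8))
  est <- mle_estimate(h)
  expect_equal(est$beta, 0.208, tolerance = 1e-4)
  expect_equal(est$se, sqrt(1 / 125), tolerance = 1e-4)

  # single SNP with negligible exposure error: Wald ratio
  h1 <- make_h(x = 0.4, y = 0.1, sigma_y = 0.03, sigma_x = 1e-6)
  expect_equal(mle_estimate(h1)$beta, 0.25, tolerance = 1e-4)
})

test_that("MLE is unbiased under its own model and beats the IVW start", {
  set.seed(33)
  k <- 4; n_reps <- 300
  xi <- c(-0.047, -0.052, -0.056, -0.027)
  sx <- c(0.013, 0.012, 0.013, 0.015)
  sy <- rep(0.05, k)
  est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    h <- make_h(x = rnorm(k, xi, sx), y = rnorm(k, 0, sy),
                sigma_y = sy, sigma_x = sx)
    est[r] <- mle_estimate(h)$beta
  }
  mc_se <- sd(est) / sqrt(n_reps)
  expect_lt(abs(mean(est)), 3 * mc_se)

  # maximized log-likelihood is at least the likelihood at the IVW start
  h <- make_h(x = rnorm(k, xi, sx), y = rnorm(k, -0.4 * xi, sy),
              sigma_y = sy, sigma_x = sx)
  fit <- mle_estimate(h, diagnostics = TRUE)
  nll_start <- vitdmr:::.mle_nll(c(ivw_estimate(h)$beta, h$x),
                                 h$x, h$sigma_x, h$y, h$sigma_y)
  nll_opt <- vitdmr:::.mle_nll(c(fit$fit$beta, fit$fit$xi),
                               h$x, h$sigma_x, h$y, h$sigma_y)
  expect_lte(nll_opt, nll_start + 1e-10)
  expect_true(fit$fit$converged)
  expect_equal(length(fit$fit$xi), k)
})

test_that("all three estimators are scale-equivariant and negation-invariant", {
  for (seed in 1:5) {
    h <- random_h(k = 8, seed = 100 + seed)
    base <- list(ivw = ivw_estimate(h)$beta,
                 mle = mle_estimate(h)$beta,
                 egg = egger_regression(h)$slope$beta)

    hc <- h; cmul <- 3.7
    hc$x <- hc$x * cmul; hc$sigma_x <- hc$sigma_x * cmul
    expect_equal(ivw_estimate(hc)$beta, base$ivw / cmul, tolerance = 1e-8)
    expect_equal(mle_estimate(hc)$beta, base$mle / cmul, tolerance = 1e-6)
    expect_equal(egger_regression(hc)$slope$beta, base$egg / cmul,
                 tolerance = 1e-8)

    hn <- h; hn$x <- -hn$x; hn$y <- -hn$y
    expect_equal(ivw_estimate(hn)$beta, base$ivw, tolerance = 1e-12)
    expect_equal(mle_estimate(hn)$beta, base$mle, tolerance = 1e-6)
    expect_equal(egger_regression(hn)$slope$beta, base$egg, tolerance = 1e-12)
  }
})

test_that("Wald summaries obey their algebraic identities", {
  ws <- wald_summary(0, 0.2)
  expect_equal(ws$or, 1.0)
  expect_equal(ws$p, 1.0)
  expect_error(wald_summary(0.1, 0), "se must be")

  set.seed(9)
  for (i in 1:20) {
    b <- rnorm(1); s <- runif(1, 0.01, 0.5)
    ws <- wald_summary(b, s)
    expect_equal(ws$or, exp(b))
    expect_true(ws$ci_low < ws$or && ws$or < ws$ci_high)
    expect_equal(ws$ci_high / ws$or, ws$or / ws$ci_low, tolerance = 1e-12)
    expect_true(ws$p > 0 && ws$p <= 1)
  }
})

test_that("estimator rows refuse excluded instruments but keep the rest", {
  h <- random_h(6, seed = 77)
  h$action[2] <- "excluded"; h$y[2] <- NA
  est <- ivw_estimate(h)
  expect_equal(est$n_snps, 5)
  expect_equal(est$beta, ivw_estimate(h[-2, ])$beta)
})
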