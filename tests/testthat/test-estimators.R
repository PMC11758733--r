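test_that("Wald ratio arithmetic, null numerator, symmetry and zero guard", {
  wr <- wald_ratio(0.5, 0.01, 0.10, 0.02)
  expect_equal(wr$beta, 0.20)
  expect_equal(wr$se, 0.04)
  wr0 <- wald_ratio(0.5, 0.01, 0, 0.02)
  expect_equal(wr0$beta, 0)
  expect_equal(wr0$se, 0.04)
  expect_equal(wald_ratio(-0.5, 0.01, -0.10, 0.02),
               wald_ratio(0.5, 0.01, 0.10, 0.02))
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02, snp_id = "rsX"), "rsX")
  # second-order SE adds the exposure-uncertainty term
  expect_equal(wald_ratio(0.5, 0.01, 0.10, 0.02, second_order = TRUE)$se,
               sqrt(0.02^2 / 0.25 + 0.01^2 * 0.01 / 0.0625))
})

test_that("single-instrument IVW degenerates to the Wald ratio", {
  h <- harmonized_set(0.5, 0.01, 0.10, 0.02)
  res <- mr_ivw(h, model = "fixed")
  expect_equal(res$beta, 0.2)
  expect_equal(res$se, 0.04)
  expect_equal(res$n_snps, 1)
  expect_error(mr_ivw(h, model = "multiplicative_random"),
               "insufficient instruments")
})

test_that("homogeneous ratios give Q = 0 and random se equals fixed se", {
  g <- c(0.1, 0.2, 0.5)
  h <- harmonized_set(g, rep(0.01, 3), 0.2 * g, g / sqrt(c(1, 4, 25)))
  fixed <- mr_ivw(h, model = "fixed")
  random <- mr_ivw(h, model = "multiplicative_random")
  expect_equal(fixed$beta, 0.2)
  expect_equal(random$beta, 0.2)
  expect_equal(random$se, fixed$se)
  expect_equal(cochran_q(h)$q_stat, 0)
})

test_that("IVW equals the WLS-through-origin oracle on 100 random instances", {
  for (i in 1:100) {
    J <- sample(3:20, 1)
    h <- random_hset(J, seed = 1000 + i)
    r <- h$records
    expect_equal(mr_ivw(h)$beta,
                 oracle_wls_origin(r$gamma_hat, r$Gamma_hat, r$sigma_y),
                 tolerance = 1e-10)
  }
  # worked three-SNP instance from the same oracle
  h <- harmonized_set(c(0.1, 0.2, 0.4), rep(0.01, 3), c(0.03, 0.04, 0.10),
                      c(0.01, 0.01, 0.02))
  r <- h$records
  expect_equal(mr_ivw(h)$beta,
               oracle_wls_origin(r$gamma_hat, r$Gamma_hat, r$sigma_y),
               tolerance = 1e-12)
})

test_that("scaling all outcome SEs by c leaves the IVW estimate and scales fixed se by c", {
  h <- random_hset(8, seed = 77)
  h2 <- h
  h2$records$sigma_y <- 3 * h$records$sigma_y
  f1 <- mr_ivw(h, model = "fixed")
  f2 <- mr_ivw(h2, model = "fixed")
  expect_equal(f2$beta, f1$beta)
  expect_equal(f2$se, 3 * f1$se)
  expect_equal(mr_ivw(h2)$beta, f1$beta)  # random-effects point estimate too
})

test_that("MR-Egger recovers an exact affine relation and matches the WLS oracle", {
  g <- c(0.05, 0.1, 0.15, 0.25)
  h <- harmonized_set(g, rep(0.01, 4), 0.05 + 0.3 * g,
                      c(0.01, 0.02, 0.015, 0.03))
  res <- mr_egger(h)
  expect_equal(res$beta, 0.3, tolerance = 1e-12)
  expect_equal(res$extra$intercept, 0.05, tolerance = 1e-12)
  expect_lt(res$extra$rss_w, 1e-20)

  # proportional data: intercept 0, slope = equal-weight IVW beta
  h0 <- harmonized_set(g, rep(0.01, 4), 0.3 * g, rep(0.02, 4))
  res0 <- mr_egger(h0)
  expect_equal(res0$extra$intercept, 0, tolerance = 1e-12)
  expect_equal(res0$beta, mr_ivw(h0)$beta, tolerance = 1e-12)

  for (i in 1:100) {
    h <- random_hset(sample(4:20, 1), seed = 2000 + i)
    r <- orient_positive(h)$records
    coef <- oracle_wls_intercept(r$gamma_hat, r$Gamma_hat, r$sigma_y)
    res <- mr_egger(h)
    expect_equal(res$extra$intercept, coef[1], tolerance = 1e-10)
    expect_equal(res$beta, coef[2], tolerance = 1e-10)
  }
  expect_error(mr_egger(harmonized_set(c(0.1, 0.2), rep(0.01, 2),
                                       c(0.02, 0.04), rep(0.02, 2))),
               "insufficient instruments")
})

test_that("weighted median equals the sample median for equal weights and odd J", {
  g <- rep(1, 3)
  h <- harmonized_set(g, rep(0.01, 3), c(0.1, 0.2, 0.3), rep(0.02, 3))
  res <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(res$beta, 0.2)
})

test_that("weighted median matches the brute-force interpolation oracle", {
  for (i in 1:100) {
    h <- random_hset(sample(3:15, 1), seed = 3000 + i)
    r <- h$records
    b <- r$Gamma_hat / r$gamma_hat
    w <- r$gamma_hat^2 / r$sigma_y^2
    res <- mr_weighted_median(h, n_boot = 10, seed = 5)
    expect_equal(res$beta, oracle_weighted_median(b, w), tolerance = 1e-12)
  }
  # dominant SNP: estimate lies in the interpolation interval next to it
  h <- harmonized_set(c(1, 0.1, 0.1), rep(0.01, 3), c(0.30, 0.01, 0.05),
                      rep(0.02, 3))
  r <- h$records
  b <- sort(r$Gamma_hat / r$gamma_hat)
  res <- mr_weighted_median(h, n_boot = 10, seed = 5)
  expect_equal(res$beta,
               oracle_weighted_median(r$Gamma_hat / r$gamma_hat,
                                      r$gamma_hat^2 / r$sigma_y^2))
  expect_gte(res$beta, b[2])
  expect_lte(res$beta, b[3])
})

test_that("weighted median bootstrap SE is reproducible for a fixed seed", {
  h <- random_hset(8, seed = 4)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(h, n_boot = 200, seed = 100)
  expect_false(identical(a$se, c$se))
})

test_that("IVW and weighted median are invariant under orientation", {
  h <- harmonized_set(c(0.2, -0.15, 0.1, -0.3), rep(0.01, 4),
                      c(0.05, -0.02, 0.01, -0.08),
                      c(0.02, 0.01, 0.03, 0.02))
  o <- orient_positive(h)
  expect_equal(mr_ivw(h)$beta, mr_ivw(o)$beta)
  expect_equal(mr_ivw(h)$se, mr_ivw(o)$se)
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(o, n_boot = 10, seed = 1)$beta)
})

test_that("odds-ratio transform matches exponentiation and the printed triple", {
  # independent arithmetic check of the back-transformed published interval
  got <- to_odds_ratio(0.2070, 0.0806)
  expect_equal(unname(got["or"]), exp(0.2070))
  expect_equal(round(unname(got["or"]), 2), 1.23)
  expect_equal(round(unname(got["ci_low"]), 2), 1.05)
  expect_equal(round(unname(got["ci_high"]), 2), 1.44)
  expect_equal(unname(got["ci_low"]), exp(0.2070 - qnorm(0.975) * 0.0806))

  null <- to_odds_ratio(0, 0.1)
  expect_equal(unname(null["or"]), 1)
  expect_equal(null[["or"]] / null[["ci_low"]], null[["ci_high"]] / null[["or"]])

  tiny <- to_odds_ratio(0.2, 1e-12)
  expect_equal(unname(tiny["ci_low"]), exp(0.2), tolerance = 1e-9)
  expect_error(to_odds_ratio(0.2, 0), "se must be positive")
  expect_error(to_odds_ratio(0.2, 0.1, level = 1.2), "level")
})

test_that("mr_result invariants hold across estimators", {
  h <- random_hset(10, seed = 5)
  for (res in list(mr_ivw(h), mr_egger(h),
                   mr_weighted_median(h, n_boot = 50, seed = 2))) {
    expect_equal(res$or, exp(res$beta), tolerance = 1e-12)
    expect_lte(res$ci_low, res$or)
    expect_gte(res$ci_high, res$or)
    expect_equal(res$n_snps, 10)
  }
})
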