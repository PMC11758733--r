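test_that("Cochran's Q: homogeneous sets give 0, two-term case matches hand sum", {
  g <- c(0.1, 0.2, 0.4)
  h <- harmonized_set(g, rep(0.01, 3), 0.25 * g, rep(0.02, 3))
  q <- cochran_q(h)
  expect_equal(q$q_stat, 0)
  expect_equal(q$q_pval, 1)
  expect_equal(q$q_df, 2)

  # J = 2, ratios 0 and 1, equal weights w: IVW beta = 1/2, Q = w/2
  h2 <- harmonized_set(c(0.1, 0.1), rep(0.01, 2), c(0, 0.1), rep(0.02, 2))
  w <- 0.1^2 / 0.02^2
  q2 <- cochran_q(h2)
  expect_equal(q2$q_stat, w / 2)
  expect_equal(q2$q_df, 1)
  expect_error(cochran_q(harmonized_set(0.1, 0.01, 0.02, 0.02)),
               "insufficient instruments")
})

test_that("Q matches a direct summation oracle on random instances", {
  for (i in 1:25) {
    h <- random_hset(sample(3:15, 1), seed = 6000 + i)
    r <- h$records
    b <- r$Gamma_hat / r$gamma_hat
    w <- r$gamma_hat^2 / r$sigma_y^2
    b_ivw <- sum(w * b) / sum(w)
    expect_equal(cochran_q(h)$q_stat, sum(w * (b - b_ivw)^2),
                 tolerance = 1e-10)
  }
})

test_that("Q relates to the random/fixed IVW se ratio when overdispersed", {
  for (i in 1:20) {
    h <- random_hset(sample(4:12, 1), seed = 7000 + i)
    J <- n_snps(h)
    res <- mr_ivw(h, model = "multiplicative_random")
    q <- cochran_q(h)$q_stat
    if (q > J - 1) {
      expect_equal((J - 1) * (res$se / res$extra$se_fixed)^2, q,
                   tolerance = 1e-10)
    } else {
      expect_equal(res$se, res$extra$se_fixed)
    }
  }
})

test_that("leave-one-out has J entries, is constant on homogeneous data, and is equivariant", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  h <- harmonized_set(g, rep(0.01, 4), 0.2 * g, rep(0.02, 4))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$beta, rep(0.2, 4))
  expect_equal(loo$excluded_snp_id, h$records$snp_id)

  # J = 2: each entry is the other SNP's Wald ratio
  h2 <- harmonized_set(c(0.1, 0.2), rep(0.01, 2), c(0.03, 0.02), rep(0.02, 2))
  loo2 <- leave_one_out(h2)
  expect_equal(loo2$beta, c(0.02 / 0.2, 0.03 / 0.1))

  # permutation equivariance
  h <- random_hset(7, seed = 12)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  hp <- h
  hp$records <- hp$records[perm, ]
  loo_a <- leave_one_out(h)
  loo_b <- leave_one_out(hp)
  expect_equal(loo_b$beta, loo_a$beta[perm])
  expect_equal(loo_b$excluded_snp_id, loo_a$excluded_snp_id[perm])
})

presso_h <- function(J, seed, theta = 0.2, outlier = NULL, shift = 0) {
  cfg <- sim_config(j_snps = J, theta = theta, seed = seed,
                    outlier_indices = if (is.null(outlier)) integer(0) else outlier,
                    outlier_shift = shift)
  sim <- simulate_two_sample(cfg)
  orient_positive(harmonize_tables(sim$exposure, sim$outcome))
}

test_that("MR-PRESSO is deterministic for a fixed seed and needs J >= 4", {
  h <- presso_h(10, seed = 21)
  a <- mr_presso(h, n_sim = 300, seed = 5)
  b <- mr_presso(h, n_sim = 300, seed = 5)
  expect_identical(a, b)
  expect_error(mr_presso(subset_hs(h, 1:3), n_sim = 100, seed = 1),
               "insufficient instruments")
})

test_that("homogeneous data yield no outliers in nearly all seeded runs", {
  clean <- 0
  for (s in 1:20) {
    h <- presso_h(20, seed = 100 + s)
    rep <- mr_presso(h, n_sim = 300, seed = s)
    if (length(rep$outliers) == 0) clean <- clean + 1
  }
  expect_gte(clean, 19)
})

test_that("a 10-residual-SD injected outlier is flagged with a significant global test", {
  # typical residual SD on the standardized scale is 1; the shift below is
  # ~10 outcome SEs at the default sample sizes
  sy_typ <- 1 / sqrt(2 * 0.25 * 100000)
  h <- presso_h(20, seed = 42, outlier = 5L, shift = 10 * sy_typ)
  rep <- mr_presso(h, n_sim = 500, seed = 11)
  expect_true("rs000005" %in% rep$outliers)
  expect_lt(rep$global_pval, 0.05)
  expect_false(is.null(rep$corrected_result))
  expect_equal(rep$corrected_result$n_snps, 20 - length(rep$outliers))
  expect_false(is.na(rep$distortion_pval))
  # removing the flagged outlier strictly decreases the observed RSS
  keep <- !(h$records$snp_id %in% rep$outliers)
  r <- h$records
  rss_full <- sum(((r$Gamma_hat - steromr:::loo_betas(r$gamma_hat, r$Gamma_hat, r$sigma_y) * r$gamma_hat) / r$sigma_y)^2)
  rk <- r[keep, ]
  rss_sub <- sum(((rk$Gamma_hat - steromr:::loo_betas(rk$gamma_hat, rk$Gamma_hat, rk$sigma_y) * rk$gamma_hat) / rk$sigma_y)^2)
  expect_lt(rss_sub, rss_full)
})

test_that("empirical p-values respect the add-one floor", {
  h <- presso_h(8, seed = 9)
  rep <- mr_presso(h, n_sim = 99, seed = 3)
  expect_gte(rep$global_pval, 1 / 100)
  expect_lte(rep$global_pval, 1)
  expect_true(all(rep$outlier_pvals >= 1 / 100))
  expect_true(all(rep$outlier_pvals <= 1))
})

test_that("sensitivity_report bundles the diagnostics and records skips", {
  h <- presso_h(10, seed = 33)
  s <- sensitivity_report(h, n_sim = 200, seed = 8)
  expect_equal(s$q_df, 9)
  expect_equal(nrow(s$loo), 10)
  expect_false(is.null(s$egger_intercept))
  expect_s3_class(s$presso, "presso_report")
  expect_length(s$skipped, 0)

  h3 <- subset_hs(h, 1:3)
  s3 <- sensitivity_report(h3, n_sim = 100, seed = 8)
  expect_null(s3$presso)
  expect_match(s3$skipped, "mr_presso")
})
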