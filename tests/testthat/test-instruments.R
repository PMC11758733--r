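test_that("p-value filter keeps exactly the sub-threshold SNPs in order", {
  p <- c(1e-6, 2e-5, 9e-6, 0.3, 1e-8)
  tab <- make_table(beta = rep(0.1, 5), se = se_for_p(0.1, p), pval = p)
  expect_message(got <- filter_by_pvalue(tab, 1e-5), "3 of 5")
  expect_equal(got$snp_id, c("rs1", "rs3", "rs5"))
  expect_equal(nrow(suppressMessages(filter_by_pvalue(tab, 1))), 5)
  expect_warning(suppressMessages(filter_by_pvalue(tab, 1e-12)),
                 "no SNPs pass")
})

test_that("p-value filtering is idempotent", {
  tab <- make_table(beta = runif(10, 0.01, 0.2), se = rep(0.02, 10))
  once <- suppressMessages(suppressWarnings(filter_by_pvalue(tab, 1e-4)))
  twice <- suppressMessages(suppressWarnings(filter_by_pvalue(once, 1e-4)))
  expect_identical(as.data.frame(twice), as.data.frame(once))
})

block_ld <- function(ids, r2val) {
  m <- matrix(r2val, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  ld_matrix(m)
}

test_that("clumping collapses one LD clump to its smallest-p SNP", {
  p <- c(1e-8, 1e-7, 1e-6)
  tab <- make_table(beta = rep(0.1, 3), se = se_for_p(0.1, p),
                    pos = c(1e6, 1e6 + 5e3, 1e6 + 1e4), pval = p)
  got <- ld_clump(tab, block_ld(tab$snp_id, 0.9))
  expect_equal(got$snp_id, "rs1")
  expect_equal(attr(got, "clump_log")$index_snp, c("rs1", "rs1"))
})

test_that("clumping never crosses chromosomes", {
  p <- c(1e-8, 1e-7, 1e-6)
  tab <- make_table(beta = rep(0.1, 3), se = se_for_p(0.1, p),
                    chrom = c("1", "2", "3"), pos = rep(1e6, 3), pval = p)
  got <- ld_clump(tab, block_ld(tab$snp_id, 0.99))
  expect_equal(nrow(got), 3)
})

test_that("greedy chain structure keeps {s1, s3, s4}", {
  # hand enumeration: s1 (smallest p) removes s2 (r2 0.5); s3 survives
  # (r2 with s1 is 0); s4 independent
  ids <- paste0("s", 1:4)
  r2 <- diag(4)
  dimnames(r2) <- list(ids, ids)
  r2["s1", "s2"] <- r2["s2", "s1"] <- 0.5
  r2["s2", "s3"] <- r2["s3", "s2"] <- 0.5
  p <- c(1e-8, 1e-7, 1e-6, 1e-5)
  tab <- make_table(beta = rep(0.1, 4), se = se_for_p(0.1, p), snp_id = ids,
                    pos = c(1e6, 1.01e6, 1.02e6, 1.03e6), pval = p)
  got <- ld_clump(tab, ld_matrix(r2))
  expect_equal(got$snp_id, c("s1", "s3", "s4"))
})

test_that("clumping is order independent and output pairs respect the threshold", {
  set.seed(11)
  J <- 12
  ids <- paste0("v", 1:J)
  r2 <- matrix(runif(J * J, 0, 0.8), J, J, dimnames = list(ids, ids))
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  ld <- ld_matrix(r2)
  tab <- make_table(beta = runif(J, 0.05, 0.2), se = rep(0.015, J),
                    snp_id = ids, pos = seq_len(J) * 1e4)
  kept <- ld_clump(tab, ld, r2_max = 0.3)
  shuffled <- tab[sample(J), ]
  kept_shuf <- ld_clump(structure(shuffled, class = class(tab)), ld,
                        r2_max = 0.3)
  expect_setequal(kept$snp_id, kept_shuf$snp_id)
  # exhaustive pair check of the clumping invariant
  for (i in seq_len(nrow(kept))) {
    for (k in seq_len(nrow(kept))) {
      if (i < k && kept$chrom[i] == kept$chrom[k] &&
          abs(kept$pos[i] - kept$pos[k]) <= 1e7) {
        expect_lte(ld$r2[kept$snp_id[i], kept$snp_id[k]], 0.3)
      }
    }
  }
})

test_that("clumping errors when a SNP is absent from a square LD matrix", {
  tab <- make_table(beta = rep(0.1, 3), se = rep(0.015, 3))
  expect_error(ld_clump(tab, block_ld(c("rs1", "rs2"), 0)),
               "missing from square LD matrix")
})

test_that("exclusion removes listed SNPs and logs the reason", {
  tab <- make_table(beta = seq(0.05, 0.19, 0.01), se = rep(0.015, 15))
  got <- exclude_snps(tab, character(0))
  expect_identical(got$snp_id, tab$snp_id)
  expect_identical(got$beta, tab$beta)
  got <- exclude_snps(tab, c("rs2", "rs9"), "confounder_associated")
  expect_equal(nrow(got), 13)
  expect_equal(nrow(attr(got, "exclusion_log")), 2)
  expect_equal(nrow(exclude_snps(tab, tab$snp_id)), 0)
})

test_that("per-SNP variance fraction matches its closed form and symmetries", {
  # independent arithmetic: e=0.5, b=0.1, s=0.01, n=1e4
  num <- 2 * 0.5 * 0.5 * 0.1^2
  den <- num + 2 * 0.5 * 0.5 * 0.01^2 * 1e4
  expect_equal(per_snp_r2(0.5, 0.1, 0.01, 1e4), num / den)
  expect_equal(per_snp_r2(0.3, 0, 0.01, 1e4), 0)
  expect_equal(per_snp_r2(0.3, 0.1, 0.01, 1e4),
               per_snp_r2(0.7, -0.1, 0.01, 1e4))
  expect_error(per_snp_r2(NA, 0.1, 0.01, 1e4), "eaf")
  expect_error(per_snp_r2(0.5, 0.1, 0.01, NA), "missing field n")
})

test_that("F-statistic evaluates its formula and guards preconditions", {
  expect_equal(f_statistic(111, 10, 0.5), 10)
  expect_equal(f_statistic(111, 10, 0), 0)
  expect_equal(f_statistic(102, 1, 0.09), 9 / 0.91)
  expect_error(f_statistic(10, 10, 0.5), "n must exceed")
  expect_error(f_statistic(100, 1, 1), "r2")
})

test_that("weak-instrument filter removes low-F SNPs and recomputes totals", {
  tab <- make_table(beta = c(0.1, 0, 0.12), se = rep(0.005, 3))
  tab$pval <- pmax(2 * pnorm(-abs(tab$beta / tab$se)), 1e-300)
  iset <- instrument_set(tab)
  got <- filter_weak_instruments(iset)
  expect_equal(got$records$snp_id, c("rs1", "rs3"))   # beta = 0 gives F = 0
  expect_equal(got$aggregate_r2, sum(got$per_snp_r2))
  expect_equal(got$aggregate_r2,
               sum(iset$per_snp_r2[c("rs1", "rs3")]))
  expect_match(got$selection_log$reason, "F = 0")

  strong <- filter_weak_instruments(instrument_set(make_table()))
  expect_equal(nrow(strong$records), 3)  # all strong: identity
})
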