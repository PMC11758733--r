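# Seeded generator of two-sample GWAS summary statistics with known causal
# effect, pleiotropy regime, LD blocks and injectable outliers.

#' Simulation configuration
#'
#' Describes the generative model for a two-sample summary-statistic pair.
#' Per SNP j: effect-allele frequency `e_j ~ U(eaf_range)`, true exposure
#' effect `gamma_j ~ N(gamma_mean, gamma_sd^2)`, exposure SE
#' `sigma_xj = 1/sqrt(2 e_j (1-e_j) n_exposure)` (continuous standardized
#' exposure), pleiotropy `alpha_j` (0; `N(0, pleiotropy_sd^2)` balanced;
#' `N(pleiotropy_mean, pleiotropy_sd^2)` directional), true outcome effect
#' `Gamma_j = theta gamma_j + alpha_j + outlier_shift 1[j in outlier_indices]`
#' on the log-odds scale, outcome SE analogous with `n_outcome`, and observed
#' effects equal to the true ones plus mean-zero normal sampling noise (or
#' exactly the true ones when `noise = FALSE`, the infinite-sample limit).
#' One run seed drives an independent per-SNP substream, so extending
#' `j_snps` leaves earlier SNPs' draws unchanged.
#'
#' Defaults emulate a steroid-hormone-sized exposure GWAS feeding a large
#' stroke case-control GWAS: a few dozen strong, uniformly oriented
#' instruments (gamma ~ N(0.1, 0.03^2), so per-SNP F is far above 10) with
#' n = 50,000 exposure / 100,000 outcome samples and a causal log-odds effect
#' of 0.2 per exposure SD.
#'
#' @param j_snps number of SNPs, >= 1.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param theta true causal effect (log-odds per exposure unit).
#' @param gamma_mean,gamma_sd distribution of true SNP-exposure effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd pleiotropy SD (forced 0 when mode is `"none"`;
#'   default 0.02 otherwise).
#' @param pleiotropy_mean pleiotropy mean (directional mode only).
#' @param outlier_indices integer indices of SNPs receiving `outlier_shift`.
#' @param outlier_shift additive outcome-effect shift for outliers.
#' @param eaf_range allele-frequency interval strictly inside (0, 1).
#' @param ld_blocks `NULL`, or `list(block_size =, within_r2 =)` for
#'   [simulate_ld_candidates()].
#' @param seed integer run seed.
#' @param noise `FALSE` gives the zero-sampling-noise limit.
#' @return a `sim_config` list.
#' @export
sim_config <- function(j_snps = 30, n_exposure = 50000, n_outcome = 100000,
                       theta = 0.2, gamma_mean = 0.1, gamma_sd = 0.03,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = NULL, pleiotropy_mean = 0,
                       outlier_indices = integer(0), outlier_shift = 0,
                       eaf_range = c(0.1, 0.9), ld_blocks = NULL,
                       seed = 1, noise = TRUE) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (is.null(pleiotropy_sd)) {
    pleiotropy_sd <- if (pleiotropy_mode == "none") 0 else 0.02
  }
  if (pleiotropy_mode == "none" && pleiotropy_sd != 0) {
    stop("config error: pleiotropy_mode 'none' requires pleiotropy_sd = 0")
  }
  if (!(j_snps >= 1)) stop("config error: j_snps must be >= 1")
  if (!(eaf_range[1] > 0 && eaf_range[2] < 1 && eaf_range[1] < eaf_range[2])) {
    stop("config error: eaf_range must lie strictly inside (0, 1)")
  }
  if (pleiotropy_sd < 0) stop("config error: pleiotropy_sd must be >= 0")
  if (any(outlier_indices < 1 | outlier_indices > j_snps)) {
    stop("config error: outlier_indices out of range")
  }
  if (!is.null(ld_blocks)) {
    stopifnot(is.list(ld_blocks), ld_blocks$block_size >= 1,
              ld_blocks$within_r2 >= 0, ld_blocks$within_r2 <= 1)
  }
  structure(list(j_snps = as.integer(j_snps), n_exposure = n_exposure,
                 n_outcome = n_outcome, theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 outlier_indices = as.integer(outlier_indices),
                 outlier_shift = outlier_shift, eaf_range = eaf_range,
                 ld_blocks = ld_blocks, seed = as.integer(seed),
                 noise = isTRUE(noise)),
            class = "sim_config")
}

# deterministic per-SNP substream seed: injective in j for fixed run seed
# (difference of two hashes is (j - j') * 2246822519 mod the Mersenne prime
# 2^31 - 1, nonzero for distinct j below the modulus); exact in doubles
substream_seed <- function(seed, j) {
  ((seed %% 2147483647) * 48271 + j * 2246822519) %% 2147483647 + 1
}

NONPAL_OTHERS <- list(A = c("C", "G"), C = c("A", "T"),
                      G = c("A", "T"), T = c("C", "G"))

#' Simulate a two-sample summary-statistic pair with known truth
#'
#' Generates exposure and outcome [sumstats] tables under the model described
#' in [sim_config()], plus the generating truth for recovery tests. Alleles
#' are drawn non-palindromic and identically oriented in both tables (use
#' [make_palindromic_fixture()] to exercise harmonization). Identical seeds
#' give bit-identical output.
#'
#' @param config a [sim_config].
#' @return list with `exposure`, `outcome` ([sumstats] tables) and `truth`
#'   (list: `theta`, `gamma`, `alpha`, `outlier_indices`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$j_snps
  eaf <- gamma <- ex <- ey <- alpha <- numeric(J)
  ea <- oa <- character(J)
  for (j in seq_len(J)) {
    withr_seed(substream_seed(config$seed, j), {
      eaf[j] <- stats::runif(1, config$eaf_range[1], config$eaf_range[2])
      gamma[j] <- stats::rnorm(1, config$gamma_mean, config$gamma_sd)
      ea[j] <- sample(c("A", "C", "G", "T"), 1)
      oa[j] <- sample(NONPAL_OTHERS[[ea[j]]], 1)
      ex[j] <- stats::rnorm(1)
      alpha[j] <- switch(config$pleiotropy_mode,
        none = 0,
        balanced = stats::rnorm(1, 0, config$pleiotropy_sd),
        directional = stats::rnorm(1, config$pleiotropy_mean,
                                   config$pleiotropy_sd))
      ey[j] <- stats::rnorm(1)
    })
  }
  sx <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
  sy <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)
  shift <- numeric(J)
  shift[config$outlier_indices] <- config$outlier_shift
  Gam <- config$theta * gamma + alpha + shift
  gamma_hat <- gamma + if (config$noise) ex * sx else 0
  Gamma_hat <- Gam + if (config$noise) ey * sy else 0

  snp_id <- sprintf("rs%06d", seq_len(J))
  chrom <- as.character((seq_len(J) - 1) %% 22 + 1)
  pos <- 1e6 + ((seq_len(J) - 1) %/% 22) * 1.5e7
  mk <- function(beta, se, n, label) {
    sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                        effect_allele = ea, other_allele = oa, eaf = eaf,
                        beta = beta, se = se,
                        pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
                        n = n, stringsAsFactors = FALSE),
             trait_label = label)
  }
  list(exposure = mk(gamma_hat, sx, config$n_exposure, "sim_exposure"),
       outcome = mk(Gamma_hat, sy, config$n_outcome, "sim_outcome"),
       truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                    outlier_indices = config$outlier_indices))
}

#' Simulate block-structured clumping candidates
#'
#' Places the SNPs in consecutive LD blocks at 1 kb spacing on one
#' chromosome (all within a single clumping window): r-squared equals
#' `within_r2` inside a block and 0 between blocks, and p-values are ordered
#' so each block's first SNP is its most significant, making the expected
#' index set exactly the block leaders.
#'
#' @param config a [sim_config] with `ld_blocks` set.
#' @return list with `table` (exposure [sumstats]) and `ld` ([ld_matrix]).
#' @export
simulate_ld_candidates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$ld_blocks)) stop("config error: ld_blocks must be set")
  J <- config$j_snps
  bs <- config$ld_blocks$block_size
  sim <- simulate_two_sample(config)
  tab <- sim$exposure
  tab$chrom <- "1"
  tab$pos <- 1e6 + (seq_len(J) - 1) * 1000
  block <- (seq_len(J) - 1) %/% bs
  within <- (seq_len(J) - 1) %% bs
  # block leader carries the smallest p in its block; block offset keeps the
  # global greedy order deterministic
  tab$pval <- 1e-8 * (1 + within) + 1e-12 * block
  r2 <- outer(block, block, `==`) * config$ld_blocks$within_r2
  diag(r2) <- 1
  dimnames(r2) <- list(tab$snp_id, tab$snp_id)
  list(table = tab, ld = ld_matrix(r2))
}

#' Palindromic-allele fixture for harmonization tests
#'
#' Simulates a two-sample pair, then rewrites the alleles of the stated
#' fraction of SNPs (the first `round(fraction * J)`) to palindromic pairs
#' (alternating A/T and C/G) in both tables.
#'
#' @param fraction fraction of SNPs made palindromic, in `[0, 1]`.
#' @param config a [sim_config].
#' @return list with `exposure` and `outcome` [sumstats] tables.
#' @export
make_palindromic_fixture <- function(fraction, config) {
  stopifnot(fraction >= 0, fraction <= 1)
  sim <- simulate_two_sample(config)
  k <- round(fraction * config$j_snps)
  if (k > 0) {
    idx <- seq_len(k)
    ea <- ifelse(idx %% 2 == 1, "A", "C")
    oa <- ifelse(idx %% 2 == 1, "T", "G")
    for (tab in c("exposure", "outcome")) {
      sim[[tab]]$effect_allele[idx] <- ea
      sim[[tab]]$other_allele[idx] <- oa
    }
  }
  list(exposure = sim$exposure, outcome = sim$outcome)
}
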