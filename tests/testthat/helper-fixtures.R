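# Shared fixtures and independent oracles used across test files.

# small well-formed summary-statistics table; pvals consistent with beta/se
make_table <- function(beta = c(0.10, 0.08, -0.12),
                       se = rep(0.01, length(beta)),
                       snp_id = paste0("rs", seq_along(beta)),
                       chrom = rep("1", length(beta)),
                       pos = seq_along(beta) * 1e6,
                       ea = rep("A", length(beta)),
                       oa = rep("G", length(beta)),
                       eaf = rep(0.3, length(beta)),
                       n = rep(50000, length(beta)),
                       pval = 2 * pnorm(-abs(beta / se)),
                       trait = "exposure") {
  sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      effect_allele = ea, other_allele = oa, eaf = eaf,
                      beta = beta, se = se, pval = pmax(pval, 1e-300), n = n,
                      stringsAsFactors = FALSE),
           trait_label = trait)
}

# subset a harmonized set by row index
subset_hs <- function(h, idx) {
  h$records <- h$records[idx, , drop = FALSE]
  rownames(h$records) <- NULL
  h
}

# standard error making a two-sided normal p-value exact for a given beta
se_for_p <- function(beta, p) abs(beta) / qnorm(1 - p / 2)

# random harmonized set for oracle comparisons
random_hset <- function(J, seed) {
  set.seed(seed)
  harmonized_set(gamma_hat = rnorm(J, 0.1, 0.05) + 0.05,
                 sigma_x = runif(J, 0.005, 0.02),
                 Gamma_hat = rnorm(J, 0.02, 0.03),
                 sigma_y = runif(J, 0.005, 0.05))
}

# oracle: IVW as weighted least squares of Gamma on gamma through the origin,
# weights 1/sigma_y^2, solved from the normal equations directly
oracle_wls_origin <- function(g, G, sy) {
  w <- 1 / sy^2
  sum(w * g * G) / sum(w * g^2)
}

# oracle: weighted regression with intercept from the explicit normal
# equations (X' W X) b = X' W y
oracle_wls_intercept <- function(g, G, sy) {
  X <- cbind(1, g)
  W <- diag(1 / sy^2)
  unname(solve(t(X) %*% W %*% X, t(X) %*% W %*% G)[, 1])
}

# oracle: weighted median by explicit sort-and-interpolate
oracle_weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  i <- max(which(p < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}
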