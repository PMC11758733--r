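# Heterogeneity and pleiotropy diagnostics: Cochran's Q, MR-PRESSO
# (global / outlier / distortion), and leave-one-out analysis.

#' Cochran's Q heterogeneity statistic
#'
#' With per-SNP ratios `b_j = Gamma_hat_j / gamma_hat_j`, weights
#' `w_j = gamma_hat_j^2 / sigma_y_j^2` and the fixed-effects IVW estimate
#' `b_IVW`, `Q = sum_j w_j (b_j - b_IVW)^2`, chi-square with J - 1 degrees of
#' freedom under homogeneity. Heterogeneous causal effects across instruments
#' are conventionally flagged at p < 0.05.
#'
#' @param set a `harmonized_set` with J >= 2.
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(set) {
  r <- set_vectors(set)
  J <- nrow(r)
  if (J < 2) stop("insufficient instruments: Cochran's Q needs J >= 2, got ", J)
  core <- ivw_core(r$gamma_hat, r$Gamma_hat, r$sigma_y)
  q <- sum(core$w * (r$Gamma_hat / r$gamma_hat - core$beta)^2)
  list(q_stat = q, q_df = J - 1,
       q_pval = stats::pchisq(q, df = J - 1, lower.tail = FALSE))
}

# leave-one-out IVW point estimates for all SNPs at once (O(J) via sum trick)
loo_betas <- function(g, G, sy) {
  w <- g^2 / sy^2
  num <- g * G / sy^2
  (sum(num) - num) / (sum(w) - w)
}

# standardized leave-one-out residuals and their weighted RSS; the PRESSO
# residual scale is sigma_y so RSS is scale-free
presso_rss <- function(g, G, sy) {
  r <- (G - loo_betas(g, G, sy) * g) / sy
  list(resid2 = r^2, rss = sum(r^2))
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Simulation-calibrated residual test for horizontal pleiotropic outliers.
#' For each SNP j the leave-one-out IVW estimate predicts its outcome effect;
#' the observed residual sum of squares (standardized by `sigma_y`) is
#' compared against `n_sim` parametric simulations with
#' `Gamma* ~ N(beta_loo_j * gamma_hat_j, sigma_y_j^2)` and
#' `gamma* ~ N(gamma_hat_j, sigma_x_j^2)`:
#' the global empirical p uses the add-one rule
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`. Per-SNP squared residuals get
#' empirical p-values against their own simulated distributions, Bonferroni
#' multiplied by J and capped at 1; SNPs below `sig` are flagged as outliers.
#' When outliers exist the outlier-corrected IVW estimate is reported along
#' with a distortion test comparing the correction against IVW estimates from
#' random same-size subsets.
#'
#' @param set a `harmonized_set` with J >= 4.
#' @param n_sim simulated datasets, default 1000.
#' @param seed integer seed (required; identical seeds give identical reports).
#' @param sig outlier significance level, default 0.05.
#' @param model IVW model for the corrected estimate.
#' @return a `presso_report`: list with `rss_obs`, `global_pval`,
#'   `outlier_pvals` (named), `outliers`, `corrected_result` (or NULL),
#'   `distortion_pval` (or NA), `n_sim`, `seed`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed, sig = 0.05,
                      model = "multiplicative_random") {
  r <- set_vectors(set)
  J <- nrow(r)
  if (J < 4) stop("insufficient instruments: MR-PRESSO needs J >= 4, got ", J)
  stopifnot(n_sim >= 1, is.numeric(seed))
  g <- r$gamma_hat; G <- r$Gamma_hat
  sx <- r$sigma_x; sy <- r$sigma_y

  obs <- presso_rss(g, G, sy)
  mu <- loo_betas(g, G, sy) * g   # null expectation of each outcome effect

  sim <- withr_seed(seed, {
    gs <- matrix(stats::rnorm(J * n_sim, g, sx), nrow = J)
    Gs <- matrix(stats::rnorm(J * n_sim, mu, sy), nrow = J)
    ws <- gs^2 / sy^2
    nums <- gs * Gs / sy^2
    bloo <- sweep(-nums, 2, colSums(nums), "+") / sweep(-ws, 2, colSums(ws), "+")
    rs2 <- ((Gs - bloo * gs) / sy)^2
    list(rss = colSums(rs2), resid2 = rs2)
  })

  global_pval <- (1 + sum(sim$rss >= obs$rss)) / (n_sim + 1)
  p_raw <- (1 + rowSums(sim$resid2 >= obs$resid2)) / (n_sim + 1)
  outlier_pvals <- pmin(1, p_raw * J)
  names(outlier_pvals) <- r$snp_id
  outliers <- r$snp_id[outlier_pvals < sig]

  corrected <- NULL
  distortion_pval <- NA_real_
  if (length(outliers) == J) {
    stop("degenerate correction: every SNP flagged as a pleiotropic outlier")
  }
  if (length(outliers) > 0) {
    keep <- !(r$snp_id %in% outliers)
    sub <- subset_set(set, keep)
    corrected <- mr_ivw(sub, model = if (sum(keep) >= 2) model else "fixed")
    full_beta <- ivw_core(g, G, sy)$beta
    d_obs <- corrected$beta - full_beta
    m <- sum(keep)
    d_sim <- withr_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        idx <- sample.int(J, m)
        ivw_core(g[idx], G[idx], sy[idx])$beta - full_beta
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(list(rss_obs = obs$rss, global_pval = global_pval,
                 outlier_pvals = outlier_pvals, outliers = outliers,
                 corrected_result = corrected,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, seed = seed),
            class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  corrected IVW beta = %.4g, distortion p = %.4g\n",
                x$corrected_result$beta, x$distortion_pval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate J times, each time excluding one SNP, to show
#' whether any single instrument drives the overall estimate. Entries follow
#' the input SNP order.
#'
#' @param set a `harmonized_set` with J >= 2.
#' @param model IVW model, see [mr_ivw()].
#' @return data frame with one row per excluded SNP: `excluded_snp_id`,
#'   `beta`, `se`, `pval`, `or`, `ci_low`, `ci_high`, `n_snps`.
#' @export
leave_one_out <- function(set, model = "multiplicative_random") {
  r <- set_vectors(set)
  J <- nrow(r)
  if (J < 2) stop("insufficient instruments: leave-one-out needs J >= 2, got ", J)
  rows <- lapply(seq_len(J), function(j) {
    sub <- subset_set(set, -j)
    res <- mr_ivw(sub, model = if (J - 1 >= 2) model else "fixed")
    data.frame(excluded_snp_id = r$snp_id[j], beta = res$beta, se = res$se,
               pval = res$pval, or = res$or, ci_low = res$ci_low,
               ci_high = res$ci_high, n_snps = res$n_snps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-out table. Components whose instrument minimum is not met are
#' set to NULL with the reason recorded in `skipped`.
#'
#' @param set a `harmonized_set`.
#' @param n_sim MR-PRESSO simulations.
#' @param seed integer seed.
#' @param sig outlier significance level.
#' @param model IVW model for leave-one-out and corrected estimates.
#' @return a `sensitivity_report` list: `q_stat`, `q_df`, `q_pval`,
#'   `egger_intercept` (intercept, se, pval), `presso`, `loo`, `skipped`.
#' @export
sensitivity_report <- function(set, n_sim = 1000, seed, sig = 0.05,
                               model = "multiplicative_random") {
  J <- n_snps(set)
  skipped <- character(0)
  q <- if (J >= 2) cochran_q(set) else {
    skipped <- c(skipped, "cochran_q: J < 2")
    list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_)
  }
  egger <- if (J >= 3) {
    e <- mr_egger(set)
    list(intercept = e$extra$intercept, intercept_se = e$extra$intercept_se,
         intercept_pval = e$extra$intercept_pval)
  } else {
    skipped <- c(skipped, "egger_intercept: J < 3")
    NULL
  }
  presso <- if (J >= 4) {
    mr_presso(set, n_sim = n_sim, seed = seed, sig = sig, model = model)
  } else {
    skipped <- c(skipped, "mr_presso: J < 4")
    NULL
  }
  loo <- if (J >= 2) leave_one_out(set, model = model) else {
    skipped <- c(skipped, "leave_one_out: J < 2")
    NULL
  }
  structure(list(q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
                 egger_intercept = egger, presso = presso, loo = loo,
                 skipped = skipped),
            class = "sensitivity_report")
}
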