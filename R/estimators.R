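# Causal estimators on harmonized summary statistics: Wald ratios, IVW,
# MR-Egger regression, weighted median, and odds-ratio reporting.
#
# Notation: per instrument j, gamma_hat (sigma_x) is the SNP-exposure effect
# (SE) and Gamma_hat (sigma_y) the SNP-outcome effect (SE) aligned to the
# exposure effect allele. The causal log-odds estimate is theta.

mr_result <- function(method, beta, se, pval, n_snps, extra = list(),
                      level = 0.95) {
  orci <- to_odds_ratio(beta, se, level = level)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or = orci[["or"]], ci_low = orci[["ci_low"]],
                 ci_high = orci[["ci_high"]], n_snps = n_snps,
                 extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.*g (SE %.*g), OR = %.*g [%.*g, %.*g], p = %.*g\n",
              x$method, x$n_snps, digits, x$beta, digits, x$se, digits, x$or,
              digits, x$ci_low, digits, x$ci_high, digits, x$pval))
  if (!is.null(x$extra$intercept)) {
    cat(sprintf("  intercept = %.*g (SE %.*g), p = %.*g\n", digits,
                x$extra$intercept, digits, x$extra$intercept_se, digits,
                x$extra$intercept_pval))
  }
  invisible(x)
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate `Gamma_hat / gamma_hat` with
#' first-order delta-method standard error `sigma_y / |gamma_hat|` (the
#' exposure SE is ignored at first order; `second_order = TRUE` adds the
#' `Gamma_hat^2 sigma_x^2 / gamma_hat^4` term under the square root).
#'
#' @param gamma_hat,sigma_x,Gamma_hat,sigma_y per-SNP effects and SEs
#'   (vectorized).
#' @param second_order include the exposure-uncertainty term in the SE?
#' @param snp_id optional ids used in error messages.
#' @return data frame with columns `beta` and `se`.
#' @export
wald_ratio <- function(gamma_hat, sigma_x, Gamma_hat, sigma_y,
                       second_order = FALSE,
                       snp_id = seq_along(gamma_hat)) {
  if (any(gamma_hat == 0)) {
    stop("division error: gamma_hat = 0 for SNP(s) ",
         paste(snp_id[gamma_hat == 0], collapse = ", "))
  }
  beta <- Gamma_hat / gamma_hat
  se <- if (second_order) {
    sqrt(sigma_y^2 / gamma_hat^2 + Gamma_hat^2 * sigma_x^2 / gamma_hat^4)
  } else {
    sigma_y / abs(gamma_hat)
  }
  data.frame(beta = beta, se = se)
}

# pull the effect vectors out of a harmonized set, refusing gamma_hat = 0
set_vectors <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  r <- set$records
  if (any(r$gamma_hat == 0)) {
    stop("division error: gamma_hat = 0 for SNP(s) ",
         paste(r$snp_id[r$gamma_hat == 0], collapse = ", "))
  }
  r
}

# IVW point estimate and fixed-effects SE (closed form); shared by the
# estimator, Cochran's Q, leave-one-out and MR-PRESSO
ivw_core <- function(g, G, sy) {
  w <- g^2 / sy^2
  beta <- sum(g * G / sy^2) / sum(w)
  list(beta = beta, se_fixed = 1 / sqrt(sum(w)), w = w)
}

#' Inverse-variance weighted estimate
#'
#' Combines the per-SNP Wald ratios with weights `w_j = gamma_hat_j^2 /
#' sigma_y_j^2`, equivalently the weighted least-squares slope of the outcome
#' effects on the exposure effects through the origin:
#' \deqn{\hat\theta_{IVW} = \frac{\sum_j \hat\gamma_j \hat\Gamma_j/\sigma_{yj}^2}
#'                               {\sum_j \hat\gamma_j^2/\sigma_{yj}^2}.}
#' The fixed-effects SE is `(sum w_j)^(-1/2)`; the multiplicative
#' random-effects model (default) inflates it by `max(1, sqrt(Q/(J-1)))` with
#' Q the Cochran heterogeneity statistic, never shrinking below the
#' fixed-effects SE. P-values use the two-sided normal reference.
#'
#' @param set a `harmonized_set` (J >= 1 for fixed, J >= 2 for random).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param level confidence level for the OR interval, default 0.95.
#' @return an `mr_result`.
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed"),
                   level = 0.95) {
  model <- match.arg(model)
  r <- set_vectors(set)
  J <- nrow(r)
  min_j <- if (model == "fixed") 1 else 2
  if (J < min_j) {
    stop("insufficient instruments: IVW (", model, ") needs J >= ", min_j,
         ", got ", J)
  }
  core <- ivw_core(r$gamma_hat, r$Gamma_hat, r$sigma_y)
  se <- core$se_fixed
  scale <- 1
  if (model == "multiplicative_random") {
    q <- sum(core$w * (r$Gamma_hat / r$gamma_hat - core$beta)^2)
    scale <- max(1, sqrt(q / (J - 1)))
    se <- se * scale
  }
  pval <- 2 * stats::pnorm(-abs(core$beta / se))
  mr_result("IVW", core$beta, se, pval, J,
            extra = list(model = model, se_fixed = core$se_fixed,
                         overdispersion_scale = scale),
            level = level)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept, `Gamma_hat_j = b0 + b1 gamma_hat_j`, weights
#' `1/sigma_y_j^2`. The slope b1 is the causal estimate; a non-zero intercept
#' b0 indicates directional horizontal pleiotropy. Because the fit depends on
#' allele orientation, the set is passed through [orient_positive()] first.
#' Coefficient SEs use multiplicative overdispersion with the residual scale
#' floored at 1, `max(1, sqrt(RSS_w/(J-2)))`; p-values are two-sided t with
#' J - 2 degrees of freedom.
#'
#' @param set a `harmonized_set` with J >= 3.
#' @param level confidence level for the OR interval, default 0.95.
#' @return an `mr_result` whose `extra` carries `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(set, level = 0.95) {
  set <- orient_positive(set)
  r <- set_vectors(set)
  J <- nrow(r)
  if (J < 3) stop("insufficient instruments: MR-Egger needs J >= 3, got ", J)
  w <- 1 / r$sigma_y^2
  sw <- sqrt(w)
  X <- cbind(intercept = 1, slope = r$gamma_hat)
  qx <- qr(X * sw)
  coefs <- qr.coef(qx, r$Gamma_hat * sw)
  resid <- r$Gamma_hat - X %*% coefs
  rss_w <- sum(w * resid^2)
  scale <- max(1, sqrt(rss_w / (J - 2)))
  xtwx_inv <- chol2inv(qr.R(qx))
  ses <- scale * sqrt(diag(xtwx_inv))
  tvals <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tvals), df = J - 2)
  mr_result("MR-Egger", unname(coefs[2]), unname(ses[2]), unname(pvals[2]), J,
            extra = list(intercept = unname(coefs[1]),
                         intercept_se = unname(ses[1]),
                         intercept_pval = unname(pvals[1]),
                         rss_w = rss_w, scale = scale),
            level = level)
}

# weighted median of ratio estimates b with weights w: sort, take cumulative
# midpoint percentiles p_j = cumsum(w') - w'/2 with w' normalized, linearly
# interpolate b against p at p = 0.5
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  stats::approx(p, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median of per-SNP Wald ratios (weights `gamma_hat^2 /
#' sigma_y^2`), consistent when valid instruments carry more than half the
#' total weight. The point estimate interpolates the sorted ratios against
#' cumulative midpoint percentiles at 50%. The SE is the standard deviation
#' of the estimate over `n_boot` parametric-bootstrap replicates resampling
#' `gamma_hat* ~ N(gamma_hat, sigma_x^2)` and `Gamma_hat* ~ N(Gamma_hat,
#' sigma_y^2)`; the p-value is two-sided normal. Reproducible for a fixed
#' `seed`.
#'
#' @param set a `harmonized_set` with J >= 3.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap (required).
#' @param level confidence level for the OR interval, default 0.95.
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed, level = 0.95) {
  r <- set_vectors(set)
  J <- nrow(r)
  if (J < 3) stop("insufficient instruments: weighted median needs J >= 3, got ", J)
  stopifnot(n_boot >= 2, is.numeric(seed))
  b <- r$Gamma_hat / r$gamma_hat
  w <- r$gamma_hat^2 / r$sigma_y^2
  est <- weighted_median_point(b, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- stats::rnorm(J, r$gamma_hat, r$sigma_x)
      G <- stats::rnorm(J, r$Gamma_hat, r$sigma_y)
      ok <- g != 0
      weighted_median_point((G / g)[ok], (g^2 / r$sigma_y^2)[ok])
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pval <- 2 * stats::pnorm(-abs(est / se))
  mr_result("weighted-median", est, se, pval, J,
            extra = list(n_boot = n_boot, seed = seed), level = level)
}

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Transform a log-odds estimate to an odds ratio with confidence interval
#'
#' `OR = exp(beta)` with bounds `exp(beta -/+ z * se)` at the standard-normal
#' quantile `z` for the requested level.
#'
#' @param beta log-odds estimate.
#' @param se its standard error, strictly positive.
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("precondition error: level must lie in (0, 1)")
  if (se <= 0) stop("precondition error: se must be positive")
  z <- stats::qnorm((1 + level) / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}
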