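# Orchestration: the full per-pair analysis, the exposure x outcome grid,
# the Bonferroni significance scheme, and report writers.

#' Analysis settings
#'
#' Collects every threshold and seed of the pipeline in one object so a run
#' is fully described by (inputs, settings). Component seeds (weighted-median
#' bootstrap, MR-PRESSO) are derived deterministically from the one run-level
#' `seed`.
#'
#' @param pval_threshold instrument p-value threshold (default 1e-5; use 5e-8
#'   for genome-wide significance when the exposure GWAS is large enough).
#' @param clump_r2,clump_kb LD-clumping thresholds (defaults 0.001 and
#'   10000 kb).
#' @param f_min weak-instrument F cutoff (default 10).
#' @param exclude character vector of confounder-associated snp_ids to remove.
#' @param palindromic palindromic-SNP policy, `"drop"` or `"infer"`.
#' @param ivw_model `"multiplicative_random"` (default) or `"fixed"`.
#' @param n_boot weighted-median bootstrap replicates (default 1000).
#' @param n_sim MR-PRESSO simulations (default 1000).
#' @param sig outlier / heterogeneity significance level (default 0.05).
#' @param seed run-level integer seed.
#' @param level confidence level (fixed default 0.95).
#' @return an `mr_settings` list.
#' @export
mr_settings <- function(pval_threshold = 1e-5, clump_r2 = 0.001,
                        clump_kb = 10000, f_min = 10, exclude = character(0),
                        palindromic = "drop", ivw_model = "multiplicative_random",
                        n_boot = 1000, n_sim = 1000, sig = 0.05, seed = 1,
                        level = 0.95) {
  structure(list(pval_threshold = pval_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min, exclude = exclude,
                 palindromic = palindromic, ivw_model = ivw_model,
                 n_boot = n_boot, n_sim = n_sim, sig = sig,
                 seed = as.integer(seed), level = level),
            class = "mr_settings")
}

#' Run the full MR analysis for one exposure-outcome pair
#'
#' Executes the pipeline: p-value filter, confounder exclusion, LD clumping
#' (when an LD matrix is supplied), per-SNP F-statistic filter, harmonization
#' to the exposure effect allele, positive orientation, the three estimators
#' (IVW, MR-Egger, weighted median) and the sensitivity battery (Cochran's Q,
#' MR-PRESSO, leave-one-out). Every dropped SNP is recorded in `log`. With
#' fewer than 3 harmonized instruments the Egger and weighted-median slots
#' carry the failure reason while IVW is still reported if J >= 1; with no
#' instruments the cell is marked failed.
#'
#' @param exposure,outcome [sumstats] tables.
#' @param settings an [mr_settings].
#' @param ld optional [ld_matrix] for clumping.
#' @return an `mr_cell` list: `exposure_label`, `outcome_label`, `status`
#'   (`"ok"` or `"failed"`), `reason`, `results` (named list ivw / egger /
#'   weighted_median), `sensitivity`, `harmonized`, `instruments`, `log`.
#' @export
run_mr_analysis <- function(exposure, outcome, settings = mr_settings(),
                            ld = NULL) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"),
            inherits(settings, "mr_settings"))
  log <- list()
  note <- function(stage, snp_id, reason) {
    if (length(snp_id) == 0) return()
    log[[length(log) + 1]] <<- data.frame(stage = stage, snp_id = snp_id,
                                          reason = reason,
                                          stringsAsFactors = FALSE)
  }
  cell <- function(status, reason = NA_character_, results = NULL,
                   sens = NULL, harm = NULL, iset = NULL) {
    structure(list(exposure_label = attr(exposure, "trait_label"),
                   outcome_label = attr(outcome, "trait_label"),
                   status = status, reason = reason, results = results,
                   sensitivity = sens, harmonized = harm, instruments = iset,
                   log = if (length(log) > 0) do.call(rbind, log) else NULL),
              class = "mr_cell")
  }

  tab <- suppressMessages(suppressWarnings(
    filter_by_pvalue(exposure, settings$pval_threshold)))
  note("pvalue_filter", setdiff(exposure$snp_id, tab$snp_id),
       paste0("p >= ", settings$pval_threshold))
  if (nrow(tab) == 0) return(cell("failed", "no_instruments"))

  if (length(settings$exclude) > 0) {
    tab2 <- exclude_snps(tab, settings$exclude)
    note("exclusion", setdiff(tab$snp_id, tab2$snp_id), "confounder_associated")
    tab <- tab2
    if (nrow(tab) == 0) return(cell("failed", "no_instruments"))
  }
  if (!is.null(ld)) {
    tab2 <- ld_clump(tab, ld, r2_max = settings$clump_r2,
                     window_kb = settings$clump_kb)
    note("clump", setdiff(tab$snp_id, tab2$snp_id), "in_ld_with_index_snp")
    tab <- tab2
  }
  iset <- instrument_set(tab)
  iset <- filter_weak_instruments(iset, f_min = settings$f_min)
  note("f_filter", setdiff(tab$snp_id, iset$records$snp_id),
       paste0("per-SNP F <= ", settings$f_min))
  if (nrow(iset$records) == 0) return(cell("failed", "no_instruments"))

  harm <- suppressWarnings(
    harmonize_tables(iset$records, outcome, policy = settings$palindromic))
  if (nrow(harm$dropped) > 0) {
    note("harmonize", harm$dropped$snp_id, harm$dropped$reason)
  }
  harm <- orient_positive(harm)
  J <- n_snps(harm)
  if (J == 0) return(cell("failed", "no_instruments", iset = iset))

  results <- list(
    ivw = mr_ivw(harm, model = if (J >= 2) settings$ivw_model else "fixed",
                 level = settings$level),
    egger = if (J >= 3) mr_egger(harm, level = settings$level) else
      paste0("insufficient instruments: J = ", J, " < 3"),
    weighted_median = if (J >= 3) {
      mr_weighted_median(harm, n_boot = settings$n_boot,
                         seed = settings$seed + 1L, level = settings$level)
    } else {
      paste0("insufficient instruments: J = ", J, " < 3")
    })
  sens <- sensitivity_report(harm, n_sim = settings$n_sim,
                             seed = settings$seed + 2L, sig = settings$sig,
                             model = settings$ivw_model)
  status <- if (J >= 3) "ok" else "failed"
  reason <- if (J >= 3) NA_character_ else "fewer_than_3_instruments"
  cell(status, reason, results = results, sens = sens, harm = harm,
       iset = iset)
}

#' Classify a p-value under the Bonferroni scheme
#'
#' The corrected significance threshold divides 0.05 by the number of
#' exposures studied (five exposures give 0.01 — the denominator counts
#' exposures, not exposure-outcome pairs). P-values between the corrected
#' threshold and the conventional 0.05 are labelled suggestive.
#'
#' @param pval p-value(s).
#' @param n_exposures number of exposures, >= 1.
#' @return character vector: `"significant"`, `"suggestive"` or `"none"`.
#' @export
classify_significance <- function(pval, n_exposures) {
  stopifnot(n_exposures >= 1)
  alpha <- 0.05 / n_exposures
  ifelse(pval < alpha, "significant",
         ifelse(pval < 0.05, "suggestive", "none"))
}

#' Run the exposure x outcome analysis grid
#'
#' Analyzes every exposure-outcome pair independently with
#' [run_mr_analysis()]; a failed cell never aborts the grid. The Bonferroni
#' threshold is derived from the exposure count and each cell's IVW p-value
#' is classified with [classify_significance()].
#'
#' @param exposures,outcomes lists of [sumstats] tables (a single table is
#'   accepted).
#' @param settings an [mr_settings].
#' @param ld optional [ld_matrix] shared by all exposures.
#' @return a `grid_result`: list with `cells` (named
#'   `"<exposure>|<outcome>"`), `significance`, `alpha_bonferroni`,
#'   `n_exposures`, `settings`.
#' @export
run_grid <- function(exposures, outcomes, settings = mr_settings(), ld = NULL) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  if (inherits(outcomes, "sumstats")) outcomes <- list(outcomes)
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1)
  n_exposures <- length(exposures)
  cells <- list()
  signif <- character(0)
  for (exp in exposures) {
    for (out in outcomes) {
      cell <- run_mr_analysis(exp, out, settings = settings, ld = ld)
      key <- paste(cell$exposure_label, cell$outcome_label, sep = "|")
      cells[[key]] <- cell
      signif[key] <- if (!is.null(cell$results) &&
                         inherits(cell$results$ivw, "mr_result")) {
        classify_significance(cell$results$ivw$pval, n_exposures)
      } else {
        NA_character_
      }
    }
  }
  structure(list(cells = cells, significance = signif,
                 alpha_bonferroni = 0.05 / n_exposures,
                 n_exposures = n_exposures, settings = settings),
            class = "grid_result")
}

cell_forest_rows <- function(cell, label) {
  rows <- lapply(cell$results, function(res) {
    if (!inherits(res, "mr_result")) return(NULL)
    data.frame(exposure = cell$exposure_label, outcome = cell$outcome_label,
               method = res$method, n_snps = res$n_snps, beta = res$beta,
               se = res$se, or = res$or, ci_low = res$ci_low,
               ci_high = res$ci_high, pval = res$pval,
               significance = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write all grid report artifacts
#'
#' Emits, under `out_dir`: `forest.tsv` (one row per cell and method with OR,
#' CI, p, SNP count and significance label), per-cell `scatter_*.tsv`
#' (per-SNP effects plus each method's fitted line, the data behind
#' scatter-plot displays), per-cell `loo_*.tsv` (leave-one-out estimates),
#' `sensitivity.tsv` (Q, Egger intercept, PRESSO global/outlier summary per
#' cell) and `manifest.json` recording every setting and seed so the run can
#' be reproduced bit-identically.
#'
#' @param grid a `grid_result`.
#' @param out_dir output directory (created if absent).
#' @return character vector of files written, invisibly.
#' @export
write_reports <- function(grid, out_dir) {
  stopifnot(inherits(grid, "grid_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }

  forest <- do.call(rbind, lapply(names(grid$cells), function(key) {
    cell_forest_rows(grid$cells[[key]], grid$significance[[key]])
  }))
  if (is.null(forest)) {
    forest <- data.frame(exposure = character(0), outcome = character(0),
                         method = character(0))
  }
  emit(forest, "forest.tsv")

  sens_rows <- list()
  for (key in names(grid$cells)) {
    cell <- grid$cells[[key]]
    slug <- gsub("[^A-Za-z0-9]+", "_", key)
    if (!is.null(cell$harmonized) && n_snps(cell$harmonized) > 0) {
      sc <- cell$harmonized$records[, c("snp_id", "gamma_hat", "sigma_x",
                                        "Gamma_hat", "sigma_y")]
      for (m in names(cell$results)) {
        res <- cell$results[[m]]
        if (inherits(res, "mr_result")) {
          sc[[paste0("fit_", m)]] <- res$beta * sc$gamma_hat +
            if (!is.null(res$extra$intercept)) res$extra$intercept else 0
        }
      }
      emit(sc, paste0("scatter_", slug, ".tsv"))
    }
    s <- cell$sensitivity
    if (!is.null(s)) {
      if (!is.null(s$loo)) emit(s$loo, paste0("loo_", slug, ".tsv"))
      sens_rows[[key]] <- data.frame(
        exposure = cell$exposure_label, outcome = cell$outcome_label,
        q_stat = s$q_stat, q_df = s$q_df, q_pval = s$q_pval,
        egger_intercept = if (!is.null(s$egger_intercept)) s$egger_intercept$intercept else NA,
        egger_intercept_pval = if (!is.null(s$egger_intercept)) s$egger_intercept$intercept_pval else NA,
        presso_global_pval = if (!is.null(s$presso)) s$presso$global_pval else NA,
        presso_outliers = if (!is.null(s$presso)) paste(s$presso$outliers, collapse = ",") else NA,
        presso_distortion_pval = if (!is.null(s$presso)) s$presso$distortion_pval else NA,
        stringsAsFactors = FALSE)
    }
  }
  emit(do.call(rbind, sens_rows), "sensitivity.tsv")

  manifest <- list(settings = unclass(grid$settings),
                   alpha_bonferroni = grid$alpha_bonferroni,
                   n_exposures = grid$n_exposures,
                   cells = names(grid$cells),
                   significance = as.list(grid$significance))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  files <- c(files, manifest_path)
  invisible(files)
}

#' @export
print.grid_result <- function(x, ...) {
  cat("MR grid: ", x$n_exposures, " exposure(s) x ",
      length(x$cells) / x$n_exposures, " outcome(s); Bonferroni alpha = ",
      x$alpha_bonferroni, "\n", sep = "")
  for (key in names(x$cells)) {
    cell <- x$cells[[key]]
    lab <- x$significance[[key]]
    if (!is.null(cell$results) && inherits(cell$results$ivw, "mr_result")) {
      r <- cell$results$ivw
      cat(sprintf("  %s: IVW OR %.3g [%.3g, %.3g], p = %.3g (%s)\n", key,
                  r$or, r$ci_low, r$ci_high, r$pval, lab))
    } else {
      cat("  ", key, ": failed (", cell$reason, ")\n", sep = "")
    }
  }
  invisible(x)
}
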