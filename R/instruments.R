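# Instrument selection: significance filter, greedy LD clumping, confounder
# exclusion, and instrument-strength (F-statistic) screening.

#' Filter summary statistics by association p-value
#'
#' Retains exactly the SNPs with `pval < threshold`, preserving input order.
#' The conventional instrument threshold for underpowered exposure GWAS is
#' 1e-5; genome-wide significance (5e-8) can be requested instead.
#'
#' @param table a [sumstats] table.
#' @param threshold p-value threshold in (0, 1].
#' @return filtered [sumstats] table; an empty result is valid (warned about).
#' @export
filter_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "sumstats"), threshold > 0, threshold <= 1)
  keep <- table$pval < threshold
  out <- table[keep, , drop = FALSE]
  message(sum(keep), " of ", nrow(table), " SNPs pass p < ", threshold)
  if (nrow(out) == 0) warning("no SNPs pass the p-value threshold")
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping to index SNPs
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as an index
#' SNP and discards all remaining SNPs on the same chromosome within
#' `window_kb` kilobases (closed interval, `|pos_a - pos_b| <= window_kb *
#' 1000`) whose r-squared with the index exceeds `r2_max`. Equal p-values are
#' broken by (chrom, pos, snp_id) lexicographic order so the result is
#' independent of input record order. Discards are recorded in the
#' `"clump_log"` attribute as (snp_id, index_snp) pairs.
#'
#' @param table a [sumstats] table with `chrom` and `pos` present.
#' @param ld an [ld_matrix]; with a square-format matrix every table SNP must
#'   be present, long-format matrices treat absent pairs as r-squared 0.
#' @param r2_max r-squared threshold, default 0.001.
#' @param window_kb window in kilobases, default 10000.
#' @return [sumstats] table of index SNPs, in input order.
#' @export
ld_clump <- function(table, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "sumstats"), inherits(ld, "ld_matrix"))
  if (any(is.na(table$chrom)) || any(is.na(table$pos))) {
    stop("precondition error: ld_clump requires chrom and pos")
  }
  if (ld$format == "square") {
    missing <- setdiff(table$snp_id, ld$snp_ids)
    if (length(missing) > 0) {
      stop("precondition error: SNP(s) missing from square LD matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  ord <- order(table$pval, table$chrom, table$pos, table$snp_id)
  remaining <- ord
  kept <- integer(0)
  log <- list()
  while (length(remaining) > 0) {
    idx <- remaining[1]
    kept <- c(kept, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- table$chrom[remaining] == table$chrom[idx]
    in_window <- abs(table$pos[remaining] - table$pos[idx]) <= window_kb * 1000
    cand <- remaining[same_chr & in_window]
    if (length(cand) > 0) {
      r2 <- ld_lookup(ld, table$snp_id[idx], table$snp_id[cand])
      drop <- cand[r2 > r2_max]
      if (length(drop) > 0) {
        log[[length(log) + 1]] <- data.frame(
          snp_id = table$snp_id[drop],
          index_snp = table$snp_id[idx],
          stringsAsFactors = FALSE)
        remaining <- setdiff(remaining, drop)
      }
    }
  }
  out <- table[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clump_log") <- if (length(log) > 0) {
    do.call(rbind, log)
  } else {
    data.frame(snp_id = character(0), index_snp = character(0))
  }
  out
}

#' Remove SNPs on a confounder exclusion list
#'
#' The exclusion list stands in for a manual phenome-wide lookup of the index
#' SNPs (e.g. PhenoScanner): SNPs associated with potential confounders are
#' supplied by the user and removed here, with the removals recorded in the
#' `"exclusion_log"` attribute.
#'
#' @param table a [sumstats] table.
#' @param exclusion_list character vector of snp_ids to remove.
#' @param reason_label label recorded with each removal.
#' @return filtered [sumstats] table.
#' @export
exclude_snps <- function(table, exclusion_list, reason_label = "confounder_associated") {
  stopifnot(inherits(table, "sumstats"))
  drop <- table$snp_id %in% exclusion_list
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- data.frame(
    snp_id = table$snp_id[drop],
    reason = rep(reason_label, sum(drop)),
    stringsAsFactors = FALSE)
  out
}

#' Read a SNP exclusion list
#'
#' TSV with a `snp_id` column and an optional second `reason` column; a
#' headerless single column of ids is also accepted.
#'
#' @param path file path.
#' @return character vector of snp_ids (reasons, if present, as names).
#' @export
read_exclusion_list <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  has_header <- first[1] == "snp_id"
  df <- utils::read.delim(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (ncol(df) >= 2) names(ids) <- as.character(df[[2]])
  ids
}

#' Per-SNP fraction of exposure variance explained
#'
#' Standardized-effect approximation: with effect-allele frequency e, per-allele
#' effect b, its standard error s and sample size n,
#' \deqn{R^2_j = \frac{2e(1-e)b^2}{2e(1-e)b^2 + 2e(1-e)s^2 n}}
#' which reduces to `2e(1-e)b^2` when the trait has unit variance; the
#' n-normalized denominator guards unstandardized inputs. Vectorized.
#'
#' @param eaf effect-allele frequency in (0,1).
#' @param beta per-allele effect.
#' @param se standard error of `beta`.
#' @param n sample size.
#' @return variance fraction in `[0, 1)`.
#' @export
per_snp_r2 <- function(eaf, beta, se, n) {
  if (any(is.na(eaf))) stop("precondition error: missing field eaf")
  if (any(is.na(n))) stop("precondition error: missing field n")
  stopifnot(all(eaf > 0 & eaf < 1), all(se > 0), all(n > 0))
  num <- 2 * eaf * (1 - eaf) * beta^2
  num / (num + 2 * eaf * (1 - eaf) * se^2 * n)
}

#' Instrument-strength F-statistic
#'
#' `F = (N - K - 1) * R^2 / (K * (1 - R^2))` with N the exposure sample size,
#' K the number of instruments and R^2 the fraction of exposure variance they
#' explain. F > 10 is the conventional weak-instrument cutoff.
#'
#' @param n sample size (must exceed `k + 1`).
#' @param k number of instruments, at least 1.
#' @param r2 variance fraction in `[0, 1)`.
#' @return non-negative F value.
#' @export
f_statistic <- function(n, k, r2) {
  if (any(r2 >= 1) || any(r2 < 0)) stop("precondition error: r2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("precondition error: n must exceed k + 1")
  if (any(k < 1)) stop("precondition error: k must be at least 1")
  (n - k - 1) * r2 / (k * (1 - r2))
}

#' Assemble an instrument set with strength statistics
#'
#' Attaches per-SNP variance fractions, their sum, and the aggregate
#' F-statistic (using the median per-SNP sample size as N) to a table of
#' selected instruments.
#'
#' @param table a [sumstats] table of selected instruments; `eaf` and `n`
#'   must be present.
#' @param exposure_label exposure name; defaults to the table's trait label.
#' @return an `instrument_set`: list with `exposure_label`, `records`,
#'   `per_snp_r2` (named), `aggregate_r2`, `f_statistic`, `selection_log`.
#' @export
instrument_set <- function(table, exposure_label = attr(table, "trait_label")) {
  stopifnot(inherits(table, "sumstats"))
  k <- nrow(table)
  if (k == 0) {
    r2 <- stats::setNames(numeric(0), character(0))
    agg <- 0
    f <- NA_real_
  } else {
    r2 <- per_snp_r2(table$eaf, table$beta, table$se, table$n)
    names(r2) <- table$snp_id
    agg <- sum(r2)
    f <- f_statistic(stats::median(table$n), k, agg)
  }
  structure(list(
    exposure_label = exposure_label,
    records = table,
    per_snp_r2 = r2,
    aggregate_r2 = agg,
    f_statistic = f,
    selection_log = data.frame(snp_id = character(0), action = character(0),
                               reason = character(0), stringsAsFactors = FALSE)
  ), class = "instrument_set")
}

#' Drop weak instruments by per-SNP F-statistic
#'
#' Each SNP's strength is `f_statistic(n_j, 1, r2_j)`; SNPs with F at or below
#' `f_min` are removed, logged in `selection_log`, and the set's aggregate
#' R-squared and F-statistic are recomputed over the survivors.
#'
#' @param set an [instrument_set].
#' @param f_min threshold, default 10.
#' @return pruned `instrument_set`.
#' @export
filter_weak_instruments <- function(set, f_min = 10) {
  stopifnot(inherits(set, "instrument_set"))
  tab <- set$records
  f_per <- f_statistic(tab$n, 1, set$per_snp_r2)
  weak <- f_per <= f_min
  out <- instrument_set(structure(tab[!weak, , drop = FALSE],
                                  class = class(tab)),
                        exposure_label = set$exposure_label)
  out$selection_log <- rbind(set$selection_log, data.frame(
    snp_id = tab$snp_id[weak],
    action = rep("removed", sum(weak)),
    reason = sprintf("per-SNP F = %.3g <= %g", f_per[weak], f_min),
    stringsAsFactors = FALSE))
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for ", x$exposure_label, ": ", nrow(x$records),
      " SNPs, aggregate R2 = ", signif(x$aggregate_r2, 4),
      ", F = ", signif(x$f_statistic, 5), "\n", sep = "")
  invisible(x)
}
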