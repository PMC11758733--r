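# Reading, validating and writing GWAS summary statistics and LD matrices.

SUMSTATS_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n")
REQUIRED_COLUMNS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")

#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data frame with one row per biallelic SNP and the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`. `eaf` (effect-allele frequency) and `n`
#' (per-SNP sample size) may be `NA`; operations that need them raise an error
#' naming the missing field. Positions are 1-based base pairs. Input row order
#' is preserved throughout the pipeline.
#'
#' @param df data frame carrying at least the required columns (`snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`); missing optional
#'   columns are filled with `NA`.
#' @param trait_label trait name attached as an attribute.
#' @param validate run [validate_sumstats()]? Default `TRUE`.
#' @return a `sumstats` data frame.
#' @export
sumstats <- function(df, trait_label = "trait", validate = TRUE) {
  stopifnot(is.data.frame(df))
  missing_req <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_req) > 0) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, SUMSTATS_COLUMNS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  rownames(df) <- NULL
  out <- structure(df, trait_label = trait_label,
                   class = c("sumstats", "data.frame"))
  if (validate) validate_sumstats(out)
  out
}

#' Validate a summary-statistics table
#'
#' Checks the type invariants: single-base A/C/G/T alleles, effect allele
#' distinct from other allele, `se > 0`, `eaf` strictly inside (0,1) where
#' present, `pval` in (0,1], unique `snp_id`. Additionally warns (does not
#' fail) when a p-value disagrees with the two-sided normal p implied by
#' `beta/se` by more than 10% relative tolerance.
#'
#' @param x a `sumstats` table.
#' @return `x`, invisibly.
#' @export
validate_sumstats <- function(x) {
  stopifnot(inherits(x, "sumstats"))
  if (anyDuplicated(x$snp_id)) {
    dup <- unique(x$snp_id[duplicated(x$snp_id)])
    stop("duplicate snp_id: ", paste(dup, collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(x$effect_allele %in% bases) | !(x$other_allele %in% bases)
  if (any(bad_allele)) {
    stop("non-single-base alleles (indel/multiallelic?) at snp_id: ",
         paste(x$snp_id[bad_allele], collapse = ", "))
  }
  if (any(x$effect_allele == x$other_allele)) {
    stop("effect_allele equals other_allele at snp_id: ",
         paste(x$snp_id[x$effect_allele == x$other_allele], collapse = ", "))
  }
  if (any(!is.finite(x$se) | x$se <= 0)) stop("se must be finite and > 0")
  if (any(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1))) {
    stop("eaf must lie strictly in (0, 1)")
  }
  if (any(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1)) {
    stop("pval must lie in (0, 1]")
  }
  if (any(!is.na(x$n) & x$n <= 0)) stop("n must be positive")
  p_implied <- 2 * stats::pnorm(-abs(x$beta / x$se))
  # only meaningful away from the underflow regime
  chk <- p_implied > 1e-300
  rel <- abs(x$pval[chk] - p_implied[chk]) / p_implied[chk]
  if (any(rel > 0.10)) {
    warning("p-values inconsistent with beta/se (two-sided normal, >10% ",
            "relative) for: ",
            paste(utils::head(x$snp_id[chk][rel > 0.10], 5), collapse = ", "))
  }
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The canonical dialect is tab-separated with header
#' `snp_id chrom pos effect_allele other_allele eaf beta se pval n`.
#' Foreign dialects (e.g. `A1`/`A2`, `freq`, `b`, `p`) are handled through an
#' explicit `column_map` rather than guessed. Alleles are upper-cased; rows
#' with non-single-base alleles or failing numeric coercion are dropped with a
#' warning reporting their row numbers.
#'
#' @param path file path.
#' @param column_map named character vector mapping file column names to
#'   canonical names, e.g. `c(SNP = "snp_id", A1 = "effect_allele")`. `NULL`
#'   means the file already uses canonical names.
#' @param trait_label trait name; defaults to the file name.
#' @return a [sumstats] table, input row order preserved.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  missing_req <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_req) > 0) {
    stop("format error: mapped columns missing ",
         paste(missing_req, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLUMNS, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, SUMSTATS_COLUMNS]
  raw$effect_allele <- toupper(raw$effect_allele)
  raw$other_allele <- toupper(raw$other_allele)

  num <- raw
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    num[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  had_value <- function(col) !is.na(raw[[col]]) & raw[[col]] != "" & raw[[col]] != "NA"
  coerce_fail <- Reduce(`|`, lapply(c("pos", "eaf", "beta", "se", "pval", "n"),
                                    function(col) is.na(num[[col]]) & had_value(col)))
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(num$effect_allele %in% bases) | !(num$other_allele %in% bases)
  bad <- coerce_fail | bad_allele
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) failing coercion or with ",
            "non-single-base alleles: row(s) ",
            paste(which(bad), collapse = ", "))
    num <- num[!bad, , drop = FALSE]
  }
  if (anyDuplicated(num$snp_id)) {
    dup <- unique(num$snp_id[duplicated(num$snp_id)])
    stop("duplicate snp_id: ", paste(dup, collapse = ", "))
  }
  if (is.null(trait_label)) trait_label <- basename(path)
  sumstats(num, trait_label = trait_label)
}

#' Write a summary-statistics table as canonical TSV
#'
#' Fixed column order (`snp_id` ... `n`), tab-separated, with full float
#' precision (17 significant digits) so that write/read round trips are
#' bit-exact.
#'
#' @param table a [sumstats] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  out <- as.data.frame(table)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct an LD matrix
#'
#' Pairwise squared-correlation (r-squared) matrix over named SNPs. The
#' diagonal is 1, values lie in `[0, 1]`, and the matrix is symmetric.
#'
#' @param r2 square numeric matrix with SNP ids as dimnames.
#' @param format `"square"` (every SNP must be present for lookups) or
#'   `"long"` (absent pairs default to r-squared 0).
#' @return an `ld_matrix` object.
#' @export
ld_matrix <- function(r2, format = c("square", "long")) {
  format <- match.arg(format)
  stopifnot(is.matrix(r2), nrow(r2) == ncol(r2),
            !is.null(rownames(r2)), identical(rownames(r2), colnames(r2)))
  if (max(abs(r2 - t(r2))) > 1e-9) stop("format error: LD matrix asymmetric beyond 1e-9")
  r2 <- (r2 + t(r2)) / 2
  if (any(r2 < 0 | r2 > 1)) stop("value error: r2 outside [0, 1]")
  diag(r2) <- 1
  structure(list(snp_ids = rownames(r2), r2 = r2, format = format),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Two dialects are accepted: a square matrix with a header row and first
#' column of SNP ids, or long format with header `snp_a  snp_b  r2` where
#' absent pairs default to r-squared 0.
#'
#' @param path file path.
#' @return an [ld_matrix] object.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (identical(header, c("snp_a", "snp_b", "r2"))) {
    long <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    ids <- unique(c(long$snp_a, long$snp_b))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_len(nrow(long))) {
      r2 <- long$r2[i]
      if (is.na(r2) || r2 < 0 || r2 > 1) stop("value error: r2 outside [0, 1]")
      m[long$snp_a[i], long$snp_b[i]] <- r2
      m[long$snp_b[i], long$snp_a[i]] <- r2
    }
    diag(m) <- 1
    ld_matrix(m, format = "long")
  } else {
    sq <- utils::read.delim(path, sep = "\t", row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(sq)
    storage.mode(m) <- "double"
    if (!identical(rownames(m), colnames(m))) {
      stop("format error: row/column SNP labels differ")
    }
    ld_matrix(m, format = "square")
  }
}

#' Write an LD matrix as square TSV
#'
#' @param ld an [ld_matrix] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- data.frame(snp_id = ld$snp_ids,
                   apply(ld$r2, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE)
  names(df) <- c("snp_id", ld$snp_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# r2 lookup between one SNP and a vector of SNPs; long-format matrices treat
# absent pairs/SNPs as r2 = 0, square-format matrices require presence.
ld_lookup <- function(ld, snp, others) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (ld$format == "square") {
    missing <- setdiff(c(snp, others), ld$snp_ids)
    if (length(missing) > 0) {
      stop("SNP(s) missing from square LD matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  out <- numeric(length(others))
  known <- others %in% ld$snp_ids
  if (snp %in% ld$snp_ids && any(known)) {
    out[known] <- ld$r2[snp, others[known]]
  }
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait_label"),
      " (", nrow(x), " SNPs)\n", sep = "")
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
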