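# Aligning exposure and outcome summary statistics to a common effect allele:
# allele-order flips, strand-complement correction, palindromic-SNP handling.

BASE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) BASE_COMPLEMENT[a1] == a2

#' Harmonize one exposure/outcome SNP pair
#'
#' Aligns the outcome association to the exposure's effect allele. Matching
#' allele pairs pass unchanged; swapped pairs have the outcome beta negated
#' and eaf replaced by 1 - eaf (`flipped`); outcome alleles that are the
#' strand complement (or complement-swapped) of the exposure's are
#' complemented first (`strand_corrected`, `strand_corrected_flipped`).
#' Palindromic SNPs (A/T or C/G) are dropped under the default policy because
#' their strand is ambiguous; the `"infer"` policy keeps a palindromic SNP
#' when both allele frequencies fall on the same side of 0.5 and outside the
#' ambiguity band 0.42-0.58. Irreconcilable allele sets are dropped as
#' mismatches.
#'
#' @param exp,out single-row [sumstats] slices (or lists) for the same snp_id.
#' @param policy `"drop"` (default) or `"infer"` for palindromic SNPs.
#' @return a list: either `list(status = "kept", record = <harmonized row>)`
#'   with fields snp_id, gamma_hat, sigma_x, Gamma_hat, sigma_y,
#'   effect_allele, other_allele, action; or `list(status = "dropped",
#'   snp_id, reason)`.
#' @export
harmonize_pair <- function(exp, out, policy = c("drop", "infer")) {
  policy <- match.arg(policy)
  if (exp$snp_id != out$snp_id) {
    stop("precondition error: snp_id mismatch (", exp$snp_id, " vs ",
         out$snp_id, ")")
  }
  dropped <- function(reason) list(status = "dropped", snp_id = exp$snp_id,
                                   reason = reason)
  e1 <- exp$effect_allele; e2 <- exp$other_allele
  o1 <- out$effect_allele; o2 <- out$other_allele

  if (is_palindromic(e1, e2) || is_palindromic(o1, o2)) {
    if (policy == "drop") return(dropped("palindromic"))
    if (is.na(exp$eaf) || is.na(out$eaf)) {
      stop("precondition error: missing field eaf (needed by palindromic ",
           "frequency inference) for ", exp$snp_id)
    }
    amb <- function(f) f > 0.42 & f < 0.58
    # outcome eaf is read on the outcome's own effect allele; for a
    # palindromic SNP the two strand readings of the same allele give f and
    # 1-f, so only clearly skewed, same-side frequencies identify the strand
    same_side <- (exp$eaf - 0.5) * (out$eaf - 0.5) > 0
    opp_side <- (exp$eaf - 0.5) * ((1 - out$eaf) - 0.5) > 0
    if (amb(exp$eaf) || amb(out$eaf)) return(dropped("palindromic_ambiguous"))
    if (!(e1 == o1 && e2 == o2) && !(e1 == o2 && e2 == o1)) {
      return(dropped("mismatch"))
    }
    straight <- e1 == o1 && e2 == o2
    if (straight && same_side) {
      return(kept_record(exp, out$beta, out$se, "unchanged", e1, e2))
    }
    if (!straight && opp_side) {
      return(kept_record(exp, -out$beta, out$se, "flipped", e1, e2))
    }
    return(dropped("palindromic_ambiguous"))
  }

  if (e1 == o1 && e2 == o2) {
    return(kept_record(exp, out$beta, out$se, "unchanged", e1, e2))
  }
  if (e1 == o2 && e2 == o1) {
    return(kept_record(exp, -out$beta, out$se, "flipped", e1, e2))
  }
  c1 <- unname(BASE_COMPLEMENT[o1]); c2 <- unname(BASE_COMPLEMENT[o2])
  if (e1 == c1 && e2 == c2) {
    return(kept_record(exp, out$beta, out$se, "strand_corrected", e1, e2))
  }
  if (e1 == c2 && e2 == c1) {
    return(kept_record(exp, -out$beta, out$se, "strand_corrected_flipped", e1, e2))
  }
  dropped("mismatch")
}

kept_record <- function(exp, Gamma_hat, sigma_y, action, ea, oa) {
  list(status = "kept",
       record = data.frame(snp_id = exp$snp_id,
                           gamma_hat = exp$beta, sigma_x = exp$se,
                           Gamma_hat = Gamma_hat, sigma_y = sigma_y,
                           effect_allele = ea, other_allele = oa,
                           action = action, stringsAsFactors = FALSE))
}

#' Harmonize two summary-statistics tables
#'
#' Intersects the tables on snp_id (keeping the exposure's input order),
#' harmonizes each pair with [harmonize_pair()], and records every drop with
#' its reason. Exposure SNPs absent from the outcome table are dropped as
#' `missing_in_outcome` (no proxy search is attempted).
#'
#' @param exp,out [sumstats] tables for exposure and outcome.
#' @param policy palindromic policy, see [harmonize_pair()].
#' @return a `harmonized_set`: list with `exposure_label`, `outcome_label`,
#'   `records` (data frame of aligned per-SNP quadruples) and `dropped`
#'   (snp_id, reason).
#' @export
harmonize_tables <- function(exp, out, policy = c("drop", "infer")) {
  policy <- match.arg(policy)
  stopifnot(inherits(exp, "sumstats"), inherits(out, "sumstats"))
  out_idx <- match(exp$snp_id, out$snp_id)
  records <- list()
  drops <- list()
  for (i in seq_len(nrow(exp))) {
    if (is.na(out_idx[i])) {
      drops[[length(drops) + 1]] <- data.frame(
        snp_id = exp$snp_id[i], reason = "missing_in_outcome",
        stringsAsFactors = FALSE)
      next
    }
    res <- harmonize_pair(exp[i, ], out[out_idx[i], ], policy = policy)
    if (res$status == "kept") {
      records[[length(records) + 1]] <- res$record
    } else {
      drops[[length(drops) + 1]] <- data.frame(
        snp_id = res$snp_id, reason = res$reason, stringsAsFactors = FALSE)
    }
  }
  empty_rec <- data.frame(snp_id = character(0), gamma_hat = numeric(0),
                          sigma_x = numeric(0), Gamma_hat = numeric(0),
                          sigma_y = numeric(0), effect_allele = character(0),
                          other_allele = character(0), action = character(0),
                          stringsAsFactors = FALSE)
  rec <- if (length(records) > 0) do.call(rbind, records) else empty_rec
  drp <- if (length(drops) > 0) {
    do.call(rbind, drops)
  } else {
    data.frame(snp_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  if (nrow(rec) == 0) warning("no SNPs shared between exposure and outcome survive harmonization")
  structure(list(exposure_label = attr(exp, "trait_label"),
                 outcome_label = attr(out, "trait_label"),
                 records = rec, dropped = drp),
            class = "harmonized_set")
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation and testing where alleles are
#' already aligned.
#'
#' @param gamma_hat,sigma_x exposure effects and their standard errors.
#' @param Gamma_hat,sigma_y outcome effects (aligned to the exposure effect
#'   allele) and their standard errors.
#' @param snp_id SNP identifiers; defaults to snp_1..snp_J.
#' @param exposure_label,outcome_label trait names.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(gamma_hat, sigma_x, Gamma_hat, sigma_y,
                           snp_id = paste0("snp_", seq_along(gamma_hat)),
                           exposure_label = "exposure",
                           outcome_label = "outcome") {
  stopifnot(all(sigma_x > 0), all(sigma_y > 0),
            length(gamma_hat) == length(Gamma_hat),
            length(gamma_hat) == length(sigma_x),
            length(gamma_hat) == length(sigma_y))
  structure(list(
    exposure_label = exposure_label, outcome_label = outcome_label,
    records = data.frame(snp_id = snp_id, gamma_hat = gamma_hat,
                         sigma_x = sigma_x, Gamma_hat = Gamma_hat,
                         sigma_y = sigma_y,
                         effect_allele = NA_character_,
                         other_allele = NA_character_,
                         action = "unchanged", stringsAsFactors = FALSE),
    dropped = data.frame(snp_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)),
    class = "harmonized_set")
}

#' Orient all exposure effects positive
#'
#' For every record with a negative exposure effect, both the exposure and
#' outcome effects are negated (equivalent to relabelling the effect allele),
#' leaving each Wald ratio unchanged. MR-Egger regression is orientation
#' dependent and requires this convention; IVW and the weighted median are
#' invariant to it. Idempotent.
#'
#' @param set a `harmonized_set`.
#' @return oriented `harmonized_set`.
#' @export
orient_positive <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  neg <- set$records$gamma_hat < 0
  set$records$gamma_hat[neg] <- -set$records$gamma_hat[neg]
  set$records$Gamma_hat[neg] <- -set$records$Gamma_hat[neg]
  if (any(neg) && !anyNA(set$records$effect_allele)) {
    ea <- set$records$effect_allele[neg]
    set$records$effect_allele[neg] <- set$records$other_allele[neg]
    set$records$other_allele[neg] <- ea
  }
  set
}

#' Number of SNPs in a harmonized set
#' @param set a `harmonized_set`.
#' @return integer SNP count.
#' @export
n_snps <- function(set) nrow(set$records)

# subset a harmonized set by logical/integer index, keeping class and labels
subset_set <- function(set, idx) {
  set$records <- set$records[idx, , drop = FALSE]
  rownames(set$records) <- NULL
  set
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", x$exposure_label, " -> ", x$outcome_label, ", ",
      nrow(x$records), " SNPs (", nrow(x$dropped), " dropped)\n", sep = "")
  invisible(x)
}

#' Write a harmonized set as TSV
#'
#' Emits the aligned per-SNP effects and the drop log beside it
#' (`<path>` and `<path>.dropped.tsv`).
#'
#' @param set a `harmonized_set`.
#' @param path output path for the records table.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(set, path) {
  stopifnot(inherits(set, "harmonized_set"))
  utils::write.table(set$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(set$dropped, paste0(path, ".dropped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
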