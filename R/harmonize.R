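#' Identify palindromic SNPs
#'
#' A SNP is palindromic when its two alleles are strand complements of each
#' other ({A,T} or {C,G}), so the coding strand cannot be resolved from the
#' alleles alone.
#'
#' @param a1,a2 Allele vectors (single nucleotides, case-insensitive).
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  unname(STRAND_COMPLEMENT[toupper(a)])
}

#' Harmonize one exposure/outcome record pair
#'
#' Expresses the outcome association on the exposure's effect allele. The
#' decision cascade: identical alleles are kept as-is; swapped alleles flip
#' the outcome (beta negated, eaf reflected); strand-complemented alleles
#' (non-palindromic SNPs only) are complemented first and then resolved as
#' identical or swapped; palindromic SNPs are handled by `policy`;
#' irreconcilable allele sets are removed as incompatible.
#'
#' Under `policy = "infer"` a palindromic SNP is retained when allele
#' frequencies on both sides are available, both minor-allele frequencies
#' are below `maf_threshold`, and the frequencies identify the strand; with
#' missing eaf on either side palindromic SNPs are always removed.
#'
#' @param exp,out Single records (one-row data frames or named lists) with
#'   fields `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`, optionally `eaf`, `n`.
#' @param policy `"remove"` (default) or `"infer"`.
#' @param maf_threshold Palindrome-inference MAF ceiling (default 0.42).
#' @return One-row tibble with the harmonized quadruple (`beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`), frequencies, and an `action` column:
#'   `kept_as_is`, `flipped_outcome`, `removed_palindromic` or
#'   `removed_incompatible`.
#' @export
harmonize_pair <- function(exp, out, policy = c("remove", "infer"),
                           maf_threshold = 0.42) {
  policy <- rlang::arg_match(policy)
  if (exp$snp_id != out$snp_id) {
    rlang::abort("records must share snp_id", class = "mrpipe_usage_error")
  }
  e <- tibble::as_tibble(exp[c("snp_id", "effect_allele", "other_allele",
                               "beta", "se", "pval")])
  names(e) <- c("snp_id", "effect_allele", "other_allele",
                "beta_exp", "se_exp", "pval_exp")
  e$eaf_exp <- if (!is.null(exp$eaf)) exp$eaf else NA_real_
  joined <- e
  joined$ea_out <- toupper(out$effect_allele)
  joined$oa_out <- toupper(out$other_allele)
  joined$beta_out <- out$beta
  joined$se_out <- out$se
  joined$pval_out <- out$pval
  joined$eaf_out <- if (!is.null(out$eaf)) out$eaf else NA_real_
  harmonize_joined(joined, policy, maf_threshold)
}

# vectorised harmonization core over a joined exposure/outcome table
harmonize_joined <- function(j, policy, maf_threshold) {
  ea <- toupper(j$effect_allele); oa <- toupper(j$other_allele)
  eb <- j$ea_out; ob <- j$oa_out
  pal <- is_palindromic(ea, oa)

  identical_al <- eb == ea & ob == oa
  swapped <- eb == oa & ob == ea
  comp_same <- !pal & complement_allele(eb) == ea & complement_allele(ob) == oa
  comp_swap <- !pal & complement_allele(eb) == oa & complement_allele(ob) == ea

  action <- rep("removed_incompatible", nrow(j))
  flip <- rep(FALSE, nrow(j))
  action[identical_al | comp_same] <- "kept_as_is"
  action[swapped | comp_swap] <- "flipped_outcome"
  flip[swapped | comp_swap] <- TRUE

  # palindromic SNPs: alleles alone cannot fix the strand
  pal_matched <- pal & (identical_al | swapped)
  if (policy == "remove") {
    action[pal_matched] <- "removed_palindromic"
  } else {
    # infer strand from allele frequencies: after the nominal allele-order
    # orientation, a frequency landing on the wrong side of 0.5 signals the
    # outcome was reported on the opposite strand, i.e. flip again
    eaf_o <- ifelse(pal_matched & swapped, 1 - j$eaf_out, j$eaf_out)
    maf_ok <- !is.na(j$eaf_exp) & !is.na(eaf_o) &
      pmin(j$eaf_exp, 1 - j$eaf_exp) < maf_threshold &
      pmin(eaf_o, 1 - eaf_o) < maf_threshold
    disagree <- (j$eaf_exp < 0.5) != (eaf_o < 0.5)
    keepable <- pal_matched & maf_ok
    action[pal_matched & !maf_ok] <- "removed_palindromic"
    strand_flip <- keepable & disagree
    flip[strand_flip] <- !flip[strand_flip]
    action[keepable] <- ifelse(flip[keepable], "flipped_outcome", "kept_as_is")
  }

  beta_out <- ifelse(flip, -j$beta_out, j$beta_out)
  eaf_out <- ifelse(flip & !is.na(j$eaf_out), 1 - j$eaf_out, j$eaf_out)

  tibble::tibble(
    snp_id = j$snp_id,
    effect_allele = ea, other_allele = oa,
    beta_exp = j$beta_exp, se_exp = j$se_exp, pval_exp = j$pval_exp,
    eaf_exp = j$eaf_exp,
    beta_out = beta_out, se_out = j$se_out, pval_out = j$pval_out,
    eaf_out = eaf_out,
    action = action)
}

#' Harmonize exposure and outcome datasets
#'
#' Inner join on `snp_id`, then per-pair harmonization (see
#' [harmonize_pair()]). Exposure SNPs absent from the outcome are logged as
#' `lost_at_outcome` (no proxy search is attempted). The returned table
#' contains only retained instruments (`kept_as_is` / `flipped_outcome`),
#' ordered by `snp_id`; removed and lost SNPs appear in the [qc_log()].
#' The result is deterministic and independent of input row order.
#'
#' @param exposure,outcome `mr_sumstats` tibbles sharing `snp_id`s.
#' @param policy,maf_threshold See [harmonize_pair()].
#' @return An `mr_harmonized` tibble with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `pval_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `pval_out`, `eaf_out`, `n_exp`,
#'   `n_out`, `action`. Sample-size columns fall back to each dataset's
#'   `n_default` attribute.
#' @export
harmonize <- function(exposure, outcome, policy = c("remove", "infer"),
                      maf_threshold = 0.42) {
  policy <- rlang::arg_match(policy)
  e <- tibble::as_tibble(exposure)
  o <- tibble::as_tibble(outcome)
  if (!"eaf" %in% names(e)) e$eaf <- NA_real_
  if (!"eaf" %in% names(o)) o$eaf <- NA_real_
  if (!"n" %in% names(e)) e$n <- attr(exposure, "n_default") %||% NA_real_
  if (!"n" %in% names(o)) o$n <- attr(outcome, "n_default") %||% NA_real_
  e$n[is.na(e$n)] <- attr(exposure, "n_default") %||% NA_real_
  o$n[is.na(o$n)] <- attr(outcome, "n_default") %||% NA_real_

  e_cols <- e[, c("snp_id", "effect_allele", "other_allele",
                  "beta", "se", "pval", "eaf", "n")]
  names(e_cols) <- c("snp_id", "effect_allele", "other_allele",
                     "beta_exp", "se_exp", "pval_exp", "eaf_exp", "n_exp")
  o_cols <- o[, c("snp_id", "effect_allele", "other_allele",
                  "beta", "se", "pval", "eaf", "n")]
  names(o_cols) <- c("snp_id", "ea_out", "oa_out",
                     "beta_out", "se_out", "pval_out", "eaf_out", "n_out")
  j <- dplyr::inner_join(e_cols, o_cols, by = "snp_id")
  lost <- setdiff(e_cols$snp_id, j$snp_id)

  h <- harmonize_joined(
    j[, c("snp_id", "effect_allele", "other_allele", "beta_exp", "se_exp",
          "pval_exp", "eaf_exp", "ea_out", "oa_out", "beta_out", "se_out",
          "pval_out", "eaf_out")],
    policy, maf_threshold)
  h$n_exp <- j$n_exp
  h$n_out <- j$n_out
  h <- dplyr::arrange(h, .data$snp_id)

  retained <- h[h$action %in% c("kept_as_is", "flipped_outcome"), , drop = FALSE]
  qc <- dplyr::bind_rows(
    new_qc_log(h$snp_id, ifelse(h$action %in% c("kept_as_is", "flipped_outcome"),
                                h$action, h$action)),
    new_qc_log(lost, rep("lost_at_outcome", length(lost))))
  qc <- dplyr::arrange(qc, .data$snp_id)

  out <- structure(retained, class = c("mr_harmonized", class(tibble::tibble())),
                   exposure_label = attr(exposure, "trait_label"),
                   outcome_label = attr(outcome, "trait_label"),
                   n_exp_default = attr(exposure, "n_default"),
                   n_out_default = attr(outcome, "n_default"))
  attach_qc(out, qc)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s, %d instrument(s)\n",
              attr(x, "exposure_label") %||% "exposure",
              attr(x, "outcome_label") %||% "outcome", nrow(x)))
  NextMethod()
}
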