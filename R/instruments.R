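#' Instrument selection
#'
#' Valid instrumental variables for two-sample Mendelian randomization must
#' be robustly associated with the exposure, mutually independent (no
#' linkage disequilibrium), strong (F statistic), and not associated with
#' confounders of the exposure-outcome relationship. The functions in this
#' file implement each screen; every stage returns the retained subset with
#' a per-SNP disposition log attached (see [qc_log()]), and the dispositions
#' always partition the stage's input exactly.
#'
#' @name instruments
NULL

new_qc_log <- function(snp_id, disposition, index_snp = NA_character_) {
  tibble::tibble(snp_id = as.character(snp_id),
                 disposition = as.character(disposition),
                 index_snp = rep_len(as.character(index_snp), length(snp_id)))
}

attach_qc <- function(out, qc) {
  attr(out, "qc_log") <- qc
  out
}

#' Retrieve the per-SNP disposition log of a selection stage
#'
#' @param x The output of [select_by_pvalue()], [greedy_clump()],
#'   [filter_weak()], [apply_blocklist()] or [harmonize()].
#' @return A tibble with columns `snp_id`, `disposition` and (for clumping)
#'   `index_snp`; one row per input SNP of that stage.
#' @export
qc_log <- function(x) {
  attr(x, "qc_log") %||% new_qc_log(character(), character())
}

#' Genome-wide significance screen
#'
#' Retains records whose association p-value is strictly below the
#' threshold, conventionally 5e-8 for genome-wide significance.
#'
#' @param dataset An `mr_sumstats` tibble.
#' @param p_threshold Significance cutoff; retention is strict (`pval <
#'   p_threshold`).
#' @return The retained subset, with a [qc_log()] marking dropped records
#'   `dropped_pvalue`. An empty result draws a warning, not an error.
#' @export
select_by_pvalue <- function(dataset, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  keep <- dataset$pval < p_threshold
  out <- dataset[keep, , drop = FALSE]
  if (inherits(dataset, "mr_sumstats")) out <- keep_sumstats_attrs(out, dataset)
  if (nrow(out) == 0) {
    rlang::warn(sprintf("no records reach p < %g", p_threshold))
  }
  attach_qc(out, new_qc_log(dataset$snp_id,
                            ifelse(keep, "retained", "dropped_pvalue")))
}

#' Greedy LD clumping
#'
#' Thins correlated instruments: repeatedly take the remaining record with
#' the smallest p-value as the index SNP, then drop every other remaining
#' record on the same chromosome within `window_kb` of it whose pairwise
#' r-squared with the index exceeds `r2_max`. Ties on p-value are broken by
#' smaller position, then lexicographic SNP id, so output is deterministic.
#'
#' Records lacking `chrom`/`pos` fall back to LD-only exclusion: they are
#' grouped on a single pseudo-chromosome with the distance condition always
#' satisfied, and a warning is emitted.
#'
#' @param dataset An `mr_sumstats` tibble.
#' @param ld An [ld_table()] (or `NULL`: all pairs unlinked, nothing
#'   clumped). Absent pairs have r2 = 0.
#' @param window_kb Clump window in kilobases (default 10,000).
#' @param r2_max LD exclusion threshold (default 0.001); a neighbour is
#'   dropped only when its r-squared with the index is strictly greater.
#' @return Retained index SNPs in original row order, with a [qc_log()]
#'   whose `dropped_clump` rows name the responsible index SNP.
#' @export
greedy_clump <- function(dataset, ld = NULL, window_kb = 10000, r2_max = 0.001) {
  stopifnot(window_kb > 0, r2_max >= 0, r2_max <= 1)
  k <- nrow(dataset)
  chrom <- if ("chrom" %in% names(dataset)) as.character(dataset$chrom) else rep(NA_character_, k)
  pos <- if ("pos" %in% names(dataset)) as.numeric(dataset$pos) else rep(NA_real_, k)
  no_coord <- is.na(chrom) | is.na(pos)
  if (any(no_coord) && k > 0) {
    rlang::warn(sprintf(
      "%d record(s) lack chrom/pos; clumping falls back to LD-only exclusion for them",
      sum(no_coord)))
  }
  chrom[is.na(chrom)] <- "unknown"

  disposition <- rep(NA_character_, k)
  index_of <- rep(NA_character_, k)
  remaining <- seq_len(k)
  # tie-break order: p, then position (NA last), then snp_id
  pos_key <- ifelse(is.na(pos), Inf, pos)
  while (length(remaining) > 0) {
    o <- order(dataset$pval[remaining], pos_key[remaining],
               dataset$snp_id[remaining])
    idx <- remaining[o[1]]
    disposition[idx] <- "retained"
    rest <- setdiff(remaining, idx)
    if (length(rest) > 0) {
      same_chr <- chrom[rest] == chrom[idx]
      within <- is.na(pos[rest]) | is.na(pos[idx]) |
        abs(pos[rest] - pos[idx]) <= window_kb * 1000
      r2 <- ld_r2(ld, dataset$snp_id[rest], rep(dataset$snp_id[idx], length(rest)))
      drop <- same_chr & within & r2 > r2_max
      disposition[rest[drop]] <- "dropped_clump"
      index_of[rest[drop]] <- dataset$snp_id[idx]
      remaining <- rest[!drop]
    } else {
      remaining <- integer()
    }
  }
  keep <- disposition == "retained"
  out <- dataset[keep, , drop = FALSE]
  if (inherits(dataset, "mr_sumstats")) out <- keep_sumstats_attrs(out, dataset)
  attach_qc(out, new_qc_log(dataset$snp_id, disposition, index_of))
}

#' Instrument-strength F statistic
#'
#' `F = beta^2 / se^2`, the square of the association z-score; F below 10
#' conventionally marks a weak instrument.
#'
#' @param beta Exposure effect estimate(s).
#' @param se Standard error(s), all > 0.
#' @return Numeric vector of F statistics (>= 0).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) {
    rlang::abort("se must be > 0", class = "mrpipe_domain_error")
  }
  (beta / se)^2
}

#' Weak-instrument filter
#'
#' Computes each record's F statistic from its exposure effect and SE, and
#' removes records with F strictly below `f_min` (F exactly at the cutoff
#' is retained). Works on both raw exposure datasets (`beta`/`se` columns)
#' and harmonized instruments (`beta_exp`/`se_exp`).
#'
#' @param dataset An `mr_sumstats` or `mr_harmonized` tibble.
#' @param f_min Minimum F retained (default 10).
#' @return The retained subset with an `f_stat` column added and a
#'   [qc_log()] marking removals `dropped_weak_F`.
#' @export
filter_weak <- function(dataset, f_min = 10) {
  if ("beta_exp" %in% names(dataset)) {
    f <- f_statistic(dataset$beta_exp, dataset$se_exp)
  } else {
    f <- f_statistic(dataset$beta, dataset$se)
  }
  keep <- f >= f_min
  out <- dataset[keep, , drop = FALSE]
  out$f_stat <- f[keep]
  if (inherits(dataset, "mr_sumstats")) out <- keep_sumstats_attrs(out, dataset)
  if (inherits(dataset, "mr_harmonized")) class(out) <- class(dataset)
  attach_qc(out, new_qc_log(dataset$snp_id,
                            ifelse(keep, "retained", "dropped_weak_F")))
}

#' Confounder blocklist exclusion
#'
#' Removes instruments whose id appears in a user-supplied blocklist of
#' SNPs associated with confounders of the exposure-outcome relationship
#' (e.g. assembled from a phenome-wide association scan).
#'
#' @param dataset An `mr_sumstats` or `mr_harmonized` tibble.
#' @param blocklist Character vector of SNP ids (see [read_blocklist()]).
#' @return The retained subset with a [qc_log()] marking removals
#'   `dropped_blocklist`; emptying the dataset draws a warning.
#' @export
apply_blocklist <- function(dataset, blocklist) {
  keep <- !(dataset$snp_id %in% blocklist)
  out <- dataset[keep, , drop = FALSE]
  if (inherits(dataset, "mr_sumstats")) out <- keep_sumstats_attrs(out, dataset)
  if (inherits(dataset, "mr_harmonized")) class(out) <- class(dataset)
  if (nrow(out) == 0 && nrow(dataset) > 0) {
    rlang::warn("blocklist removed every record")
  }
  attach_qc(out, new_qc_log(dataset$snp_id,
                            ifelse(keep, "retained", "dropped_blocklist")))
}
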