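#' Canonical column mapping for GWAS summary-statistics files
#'
#' GWAS consortia export summary statistics under many column dialects.
#' `sumstats_columns()` builds an explicit mapping from the canonical names
#' used throughout this package to the column names found in a particular
#' file. Unstated entries keep their defaults; set an optional column to
#' `NA` to declare it absent.
#'
#' @param snp,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n,n_case,n_control
#'   Column name in the file for each canonical field. `snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se` and `pval` are required
#'   in any file; the rest are optional.
#' @return A named character vector (canonical name -> file column name).
#' @examples
#' sumstats_columns(snp = "rsid", pval = "p_value")
#' @export
sumstats_columns <- function(snp = "snp", chrom = "chr", pos = "pos",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele", eaf = "eaf",
                             beta = "beta", se = "se", pval = "pval",
                             n = "n", n_case = "ncase", n_control = "ncontrol") {
  c(snp_id = snp, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval,
    n = n, n_case = n_case, n_control = n_control)
}

REQUIRED_COLS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Validate and classify summary-statistic rows
#'
#' Hard invariants (violations reject the row): single-nucleotide A/C/G/T
#' alleles with effect != other, finite beta, se > 0, pval in (0, 1], and
#' eaf in (0, 1) when present. A soft consistency check compares the
#' reported p-value with the two-sided normal p implied by |beta/se|; rows
#' disagreeing by more than a factor of 10 draw a warning but are kept.
#'
#' @noRd
validate_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, msg, reason)
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  reason <- flag(is.na(df$snp_id) | df$snp_id == "", "missing snp id")
  reason <- flag(!(df$effect_allele %in% VALID_ALLELES) |
                   !(df$other_allele %in% VALID_ALLELES),
                 "allele not a single A/C/G/T nucleotide")
  reason <- flag(df$effect_allele == df$other_allele, "identical alleles")
  reason <- flag(!is.finite(df$beta), "non-finite beta")
  reason <- flag(!is.finite(df$se) | df$se <= 0, "se not > 0")
  reason <- flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
                 "pval outside (0, 1]")
  if ("eaf" %in% names(df)) {
    bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
    reason <- ifelse(is.na(reason) & bad_eaf, "eaf outside (0, 1)", reason)
  }
  ok <- is.na(reason)

  implied <- 2 * stats::pnorm(-abs(df$beta[ok] / df$se[ok]))
  off <- implied > 1e-300 & df$pval[ok] > 1e-300 &
    abs(log10(implied) - log10(df$pval[ok])) > 1
  if (any(off, na.rm = TRUE)) {
    rlang::warn(sprintf(
      "%d row(s) have a reported p-value more than 10-fold from the normal p implied by beta/se",
      sum(off, na.rm = TRUE)))
  }
  list(ok = ok, reason = reason)
}

new_sumstats <- function(df, trait_label, trait_type, n_default,
                         load_report = NULL) {
  out <- tibble::as_tibble(df)
  structure(out,
            class = c("mr_sumstats", class(out)),
            trait_label = trait_label,
            trait_type = trait_type,
            n_default = n_default,
            load_report = load_report)
}

#' Coerce a data frame to a validated summary-statistics dataset
#'
#' @param df A data frame with canonical columns (`snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`; optionally
#'   `chrom`, `pos`, `eaf`, `n`, `n_case`, `n_control`).
#' @param trait_label Human-readable trait name.
#' @param trait_type `"binary"` or `"continuous"`; binary traits carry
#'   log-odds effect sizes.
#' @param n_default Sample size to assume when no per-SNP `n` column is
#'   present (used by the Steiger test).
#' @return A tibble of class `mr_sumstats`. Rows violating hard invariants
#'   are dropped and recorded, with row numbers and reasons, in the
#'   `load_report` attribute (see [load_report()]).
#' @export
as_sumstats <- function(df, trait_label = "trait",
                        trait_type = c("continuous", "binary"),
                        n_default = NA_real_) {
  trait_type <- rlang::arg_match(trait_type)
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("required column(s) missing: %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "mrpipe_config_error")
  }
  df <- tibble::as_tibble(df)
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  v <- validate_rows(df)
  report <- tibble::tibble(row = which(!v$ok),
                           snp_id = df$snp_id[!v$ok],
                           reason = v$reason[!v$ok])
  new_sumstats(df[v$ok, , drop = FALSE], trait_label, trait_type,
               n_default, load_report = report)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a header-bearing tab-separated file, renames columns to canonical
#' names via `column_map`, uppercases alleles, and validates every row.
#' Rows that violate hard invariants (non-SNP alleles, `se <= 0`, p-values
#' outside (0, 1], allele frequencies outside (0, 1)) are rejected, with
#' original file row numbers collected in the load report rather than
#' aborting the read.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Output of [sumstats_columns()] naming the file's
#'   columns.
#' @param trait_label,trait_type,n_default See [as_sumstats()].
#' @return An `mr_sumstats` tibble; inspect rejected rows with
#'   [load_report()].
#' @seealso [write_sumstats()], [dedup_records()]
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(),
                          trait_label = "trait",
                          trait_type = c("continuous", "binary"),
                          n_default = NA_real_) {
  trait_type <- rlang::arg_match(trait_type)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req_file_cols <- column_map[REQUIRED_COLS]
  absent <- req_file_cols[!req_file_cols %in% names(raw)]
  if (length(absent) > 0) {
    rlang::abort(sprintf("column(s) named in column_map not found in %s: %s",
                         path, paste(absent, collapse = ", ")),
                 class = "mrpipe_config_error")
  }
  present <- column_map[!is.na(column_map) & column_map %in% names(raw)]
  df <- raw[, unname(present), drop = FALSE]
  names(df) <- names(present)

  numeric_cols <- intersect(c("pos", "eaf", "beta", "se", "pval",
                              "n", "n_case", "n_control"), names(df))
  bad_numeric <- rep(FALSE, nrow(df))
  for (cc in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[cc]]))
    bad_numeric <- bad_numeric | (!is.na(df[[cc]]) & is.na(parsed))
    df[[cc]] <- parsed
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  v <- validate_rows(df)
  ok <- v$ok & !bad_numeric
  reason <- ifelse(bad_numeric, "unparseable numeric field", v$reason)
  report <- tibble::tibble(row = which(!ok),
                           snp_id = df$snp_id[!ok],
                           reason = reason[!ok])
  new_sumstats(df[ok, , drop = FALSE], trait_label, trait_type,
               n_default, load_report = report)
}

#' Retrieve the row-rejection report from a loaded dataset
#'
#' @param x An `mr_sumstats` object.
#' @return A tibble with columns `row`, `snp_id`, `reason`; zero rows when
#'   every input row validated.
#' @export
load_report <- function(x) {
  rep <- attr(x, "load_report")
  if (is.null(rep)) tibble::tibble(row = integer(), snp_id = character(),
                                   reason = character()) else rep
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("<mr_sumstats> %s (%s), %d SNPs",
              attr(x, "trait_label") %||% "trait",
              attr(x, "trait_type") %||% "?", nrow(x)))
  rej <- load_report(x)
  if (nrow(rej) > 0) cat(sprintf(", %d rows rejected at load", nrow(rej)))
  cat("\n")
  NextMethod()
}

keep_sumstats_attrs <- function(out, template) {
  new_sumstats(out,
               trait_label = attr(template, "trait_label"),
               trait_type = attr(template, "trait_type"),
               n_default = attr(template, "n_default"),
               load_report = attr(template, "load_report"))
}

#' Collapse duplicated SNP records
#'
#' When the same `snp_id` occurs more than once, only the record with the
#' smallest p-value is retained; ties keep the first occurrence. The number
#' removed is recorded in the `dedup_removed` attribute.
#'
#' @param dataset An `mr_sumstats` tibble (or plain data frame with the
#'   canonical columns).
#' @return The dataset with unique `snp_id`, original row order preserved
#'   among kept records.
#' @export
dedup_records <- function(dataset) {
  ord <- seq_len(nrow(dataset))
  keep <- !duplicated(dataset$snp_id[order(dataset$pval, ord)])
  keep <- keep[order(order(dataset$pval, ord))]  # back to original order
  out <- dataset[keep, , drop = FALSE]
  n_removed <- nrow(dataset) - nrow(out)
  if (inherits(dataset, "mr_sumstats")) out <- keep_sumstats_attrs(out, dataset)
  attr(out, "dedup_removed") <- n_removed
  out
}

#' Write a summary-statistics dataset to TSV
#'
#' Canonical columns round-trip byte-identically through
#' [read_sumstats()] with the default column map.
#'
#' @param dataset An `mr_sumstats` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  out <- tibble::as_tibble(dataset)
  rename_back <- c(snp_id = "snp", chrom = "chr")
  for (nm in names(rename_back)) {
    if (nm %in% names(out)) names(out)[names(out) == nm] <- rename_back[[nm]]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a long-format LD table
#'
#' Expects a TSV with columns `snp_a`, `snp_b`, `r2`. Rows with `r2`
#' outside \[0, 1\] are rejected and listed (with row numbers) in the
#' `rejected` attribute. Absent pairs are treated as unlinked (r2 = 0) on
#' lookup, and the table is symmetric: r2(a, b) = r2(b, a), r2(a, a) = 1.
#'
#' @param path Path to the TSV.
#' @return An object of class `mr_ld_table`.
#' @seealso [ld_r2()]
#' @export
read_ld_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(df) <- c("snp_a", "snp_b", "r2")
  bad <- !is.finite(df$r2) | df$r2 < 0 | df$r2 > 1
  rejected <- tibble::tibble(row = which(bad), r2 = df$r2[bad])
  ld_table(df[!bad, , drop = FALSE], rejected = rejected)
}

#' Construct an LD table from a data frame
#'
#' @param entries Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @param rejected Internal; rejected-row report from [read_ld_table()].
#' @return An object of class `mr_ld_table`.
#' @export
ld_table <- function(entries = NULL, rejected = NULL) {
  if (is.null(entries)) {
    entries <- tibble::tibble(snp_a = character(), snp_b = character(),
                              r2 = double())
  }
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(entries)))
  if (any(entries$r2 < 0 | entries$r2 > 1)) {
    rlang::abort("r2 values must lie in [0, 1]")
  }
  key <- paste(pmin(entries$snp_a, entries$snp_b),
               pmax(entries$snp_a, entries$snp_b), sep = "\r")
  structure(list(entries = tibble::as_tibble(entries), key = key,
                 rejected = rejected %||%
                   tibble::tibble(row = integer(), r2 = double())),
            class = "mr_ld_table")
}

#' Look up pairwise LD
#'
#' Symmetric lookup into an [ld_table()]: `ld_r2(ld, a, b)` equals
#' `ld_r2(ld, b, a)`; a SNP with itself returns 1; pairs absent from the
#' table return 0 (long-format LD tables are sparse by construction).
#'
#' @param ld An `mr_ld_table`, or `NULL` (all pairs unlinked).
#' @param a,b Character vectors of SNP ids (recycled to common length).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld) && nrow(ld$entries) > 0) {
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    idx <- match(key, ld$key)
    hit <- !is.na(idx) & a != b
    out[hit] <- ld$entries$r2[idx[hit]]
  }
  out
}

#' @export
print.mr_ld_table <- function(x, ...) {
  cat(sprintf("<mr_ld_table> %d pair(s)", nrow(x$entries)))
  if (nrow(x$rejected) > 0) cat(sprintf(", %d row(s) rejected", nrow(x$rejected)))
  cat("\n")
  invisible(x)
}

#' Read a SNP blocklist
#'
#' One SNP id per line; blank lines and `#` comments ignored. Used to
#' exclude instruments associated with known confounders of the
#' exposure-outcome relationship (standing in for interactive
#' phenome-scanner lookups).
#'
#' @param path Path to the plain-text file.
#' @return Character vector of unique SNP ids.
#' @export
read_blocklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
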