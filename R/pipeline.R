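#' Configure an end-to-end MR analysis
#'
#' Collects every knob of the pipeline in one structured object so a run
#' is fully reproducible from its config and seed.
#'
#' @param exposure,outcome Either `mr_sumstats` objects or file paths
#'   (read with `exposure_columns`/`outcome_columns` maps).
#' @param exposure_columns,outcome_columns [sumstats_columns()] maps used
#'   when the corresponding input is a path.
#' @param exposure_label,outcome_label Trait labels used in reports when
#'   inputs are paths.
#' @param p_threshold,clump_kb,clump_r2 Instrument-selection parameters
#'   (genome-wide screen and greedy clumping).
#' @param ld An [ld_table()] or a path to a long-format LD TSV; `NULL`
#'   treats all pairs as unlinked.
#' @param blocklist Character vector of SNP ids or a path to a blocklist
#'   file; `NULL` skips the confounder screen.
#' @param f_min Weak-instrument F cutoff.
#' @param palindrome_policy `"remove"` or `"infer"`.
#' @param methods Estimators to run (see [mr_estimate()]).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_n_sim,presso_threshold MR-PRESSO parameters.
#' @param n_exp,n_out Optional scalar GWAS sample sizes for the Steiger
#'   test (otherwise taken from the data).
#' @param seed Master seed for all stochastic steps (weighted-median
#'   bootstrap, MR-PRESSO simulations).
#' @return A list of class `mr_config`.
#' @export
analysis_config <- function(exposure, outcome,
                            exposure_columns = sumstats_columns(),
                            outcome_columns = sumstats_columns(),
                            exposure_label = "exposure",
                            outcome_label = "outcome",
                            p_threshold = 5e-8, clump_kb = 10000,
                            clump_r2 = 0.001, ld = NULL, blocklist = NULL,
                            f_min = 10,
                            palindrome_policy = c("remove", "infer"),
                            methods = c("ivw", "egger", "weighted_median"),
                            n_boot = 1000, presso_n_sim = 1000,
                            presso_threshold = 0.05,
                            n_exp = NULL, n_out = NULL, seed = 1L) {
  palindrome_policy <- rlang::arg_match(palindrome_policy)
  structure(list(exposure = exposure, outcome = outcome,
                 exposure_columns = exposure_columns,
                 outcome_columns = outcome_columns,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label,
                 p_threshold = p_threshold, clump_kb = clump_kb,
                 clump_r2 = clump_r2, ld = ld, blocklist = blocklist,
                 f_min = f_min, palindrome_policy = palindrome_policy,
                 methods = methods, n_boot = n_boot,
                 presso_n_sim = presso_n_sim,
                 presso_threshold = presso_threshold,
                 n_exp = n_exp, n_out = n_out, seed = as.integer(seed)),
            class = "mr_config")
}

resolve_input <- function(x, columns, label, role) {
  if (inherits(x, "mr_sumstats")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_sumstats(x, column_map = columns, trait_label = label))
  }
  if (is.data.frame(x)) return(as_sumstats(x, trait_label = label))
  rlang::abort(sprintf("%s must be an mr_sumstats, data frame, or file path", role),
               class = "mrpipe_config_error")
}

#' Run the full two-sample MR analysis
#'
#' Executes the fixed stage order: duplicate collapse on both datasets,
#' genome-wide significance screen, greedy LD clumping, allele
#' harmonization, weak-instrument (F) filter, confounder blocklist — then
#' the estimator panel, the sensitivity diagnostics, and the Steiger
#' directionality test. Methods whose instrument minimum is not met are
#' skipped with an explicit report entry; the rest still run. Identical
#' config and inputs produce identical output.
#'
#' @param config An [analysis_config()].
#' @return An object of class `mr_report`: list with
#'   \describe{
#'     \item{qc}{Stage-count ledger (tibble `stage`, `n_removed`,
#'       `n_remaining`): counts sum exactly from extracted to final.}
#'     \item{qc_detail}{Per-SNP dispositions across all stages.}
#'     \item{results}{Estimator panel table (see [mr_estimate()]).}
#'     \item{sensitivity}{[sensitivity_report()] output.}
#'     \item{steiger}{[steiger_test()] output.}
#'     \item{harmonized}{Final instrument set.}
#'     \item{loo, funnel}{Leave-one-out and funnel-plot tables.}
#'     \item{skipped}{Named skip reasons for methods that could not run.}
#'     \item{provenance}{Config hash, seed, package version.}
#'   }
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  exposure <- resolve_input(config$exposure, config$exposure_columns,
                            config$exposure_label, "exposure")
  outcome <- resolve_input(config$outcome, config$outcome_columns,
                           config$outcome_label, "outcome")
  ld <- config$ld
  if (is.character(ld)) ld <- read_ld_table(ld)
  blocklist <- config$blocklist
  if (is.character(blocklist) && length(blocklist) == 1 && file.exists(blocklist)) {
    blocklist <- read_blocklist(blocklist)
  }

  exposure <- dedup_records(exposure)
  outcome <- dedup_records(outcome)

  qc_detail <- list()
  sig <- select_by_pvalue(exposure, config$p_threshold)
  qc_detail$pvalue <- qc_log(sig)
  clumped <- greedy_clump(sig, ld = ld, window_kb = config$clump_kb,
                          r2_max = config$clump_r2)
  qc_detail$clump <- qc_log(clumped)
  n_extracted <- nrow(clumped)

  harm <- harmonize(clumped, outcome, policy = config$palindrome_policy)
  qc_detail$harmonize <- qc_log(harm)
  hlog <- qc_log(harm)
  n_lost <- sum(hlog$disposition == "lost_at_outcome")
  n_pal <- sum(hlog$disposition == "removed_palindromic")
  n_incomp <- sum(hlog$disposition == "removed_incompatible")

  strong <- filter_weak(harm, f_min = config$f_min)
  qc_detail$weak <- qc_log(strong)
  n_weak <- nrow(harm) - nrow(strong)

  final <- strong
  n_block <- 0
  if (!is.null(blocklist)) {
    final <- apply_blocklist(strong, blocklist)
    qc_detail$blocklist <- qc_log(final)
    n_block <- nrow(strong) - nrow(final)
  }

  qc <- tibble::tibble(
    stage = c("extracted", "lost_at_outcome", "removed_palindromic",
              "removed_incompatible", "removed_weak_F", "removed_blocklist",
              "final"),
    n_removed = c(0L, n_lost, n_pal, n_incomp, n_weak, n_block, 0L),
    n_remaining = c(n_extracted, n_extracted - n_lost,
                    n_extracted - n_lost - n_pal,
                    n_extracted - n_lost - n_pal - n_incomp,
                    n_extracted - n_lost - n_pal - n_incomp - n_weak,
                    nrow(final), nrow(final)))

  results <- mr_estimate(final, methods = config$methods, model = "random",
                         n_boot = config$n_boot, seed = config$seed)
  skipped <- attr(results, "skipped") %||% character()
  sens <- sensitivity_report(final, presso_n_sim = config$presso_n_sim,
                             presso_threshold = config$presso_threshold,
                             seed = config$seed)
  skipped <- c(skipped, sens$skipped)
  steiger <- if (nrow(final) >= 1) {
    steiger_test(final, n_exp = config$n_exp, n_out = config$n_out)
  } else NULL

  cfg_for_hash <- config
  cfg_for_hash$exposure <- NULL
  cfg_for_hash$outcome <- NULL
  structure(list(
    exposure_label = attr(exposure, "trait_label") %||% config$exposure_label,
    outcome_label = attr(outcome, "trait_label") %||% config$outcome_label,
    qc = qc, qc_detail = dplyr::bind_rows(qc_detail, .id = "stage"),
    results = results, sensitivity = sens, steiger = steiger,
    harmonized = final,
    loo = sens$loo %||% tibble::tibble(),
    funnel = sens$funnel, skipped = skipped,
    provenance = list(config_hash = rlang::hash(cfg_for_hash),
                      seed = config$seed,
                      version = as.character(utils::packageVersion("mrpipe")))),
    class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %s -> %s (%d instruments)\n",
              x$exposure_label, x$outcome_label, nrow(x$harmonized)))
  cat("\nCausal estimates:\n")
  print(x$results)
  if (!is.null(x$sensitivity)) {
    cat("\nSensitivity:\n")
    print(tidy(x$sensitivity))
  }
  if (!is.null(x$steiger)) {
    cat("\nDirectionality:\n")
    print(tidy(x$steiger))
  }
  if (length(x$skipped) > 0) {
    cat("\nSkipped:\n")
    for (nm in names(x$skipped)) cat(sprintf("  %s: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}

#' @rdname run_analysis
#' @param x An `mr_report`.
#' @param ... Unused.
#' @method tidy mr_report
#' @export
tidy.mr_report <- function(x, ...) {
  dplyr::mutate(x$results, exposure = x$exposure_label,
                outcome = x$outcome_label, .before = 1)
}

#' @rdname run_analysis
#' @method glance mr_report
#' @export
glance.mr_report <- function(x, ...) {
  sens <- if (is.null(x$sensitivity)) tibble::tibble() else tidy(x$sensitivity)
  st <- if (is.null(x$steiger)) tibble::tibble() else tidy(x$steiger)
  dplyr::bind_cols(
    tibble::tibble(exposure = x$exposure_label, outcome = x$outcome_label,
                   n_snp = nrow(x$harmonized)),
    sens, st)
}

format_num <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}

#' Write report tables to disk
#'
#' Emits the standard output files of a run: `results.tsv` (one row per
#' estimator: Exposure, Method, nSNP, Beta, OR, CI_low, CI_high, P),
#' `sensitivity.tsv` (Egger intercept and its P, Q and its P, MR-PRESSO
#' global P before correction and corrected P after outlier removal — NA
#' when no outliers were flagged), `harmonized.tsv`, `loo.tsv`,
#' `funnel.tsv` and `qc_log.tsv`. Reruns of the same report produce
#' byte-identical files.
#'
#' @param report An `mr_report`.
#' @param out_dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report_tables <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- tibble::tibble(
    Exposure = rep(report$exposure_label, nrow(report$results)),
    Method = report$results$method,
    nSNP = report$results$n_snp,
    Beta = report$results$beta,
    OR = report$results$or_,
    CI_low = report$results$ci_low,
    CI_high = report$results$ci_high,
    P = report$results$pval)
  readr::write_tsv(res, file.path(out_dir, "results.tsv"), progress = FALSE)

  s <- if (is.null(report$sensitivity)) {
    tibble::tibble(egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                   q = NA_real_, q_p = NA_real_, presso_global_p = NA_real_,
                   presso_corrected_p = NA_real_,
                   presso_n_outliers = NA_integer_)
  } else {
    tidy(report$sensitivity)
  }
  sens <- tibble::tibble(
    Exposure = report$exposure_label, Outcome = report$outcome_label,
    Egger_intercept = s$egger_intercept, Egger_intercept_P = s$egger_intercept_p,
    Q = s$q, Q_P = s$q_p,
    PRESSO_before_P = s$presso_global_p,
    PRESSO_after_P = s$presso_corrected_p)
  readr::write_tsv(sens, file.path(out_dir, "sensitivity.tsv"), progress = FALSE)

  readr::write_tsv(tibble::as_tibble(report$harmonized),
                   file.path(out_dir, "harmonized.tsv"), progress = FALSE)
  readr::write_tsv(report$loo, file.path(out_dir, "loo.tsv"), progress = FALSE)
  readr::write_tsv(report$funnel, file.path(out_dir, "funnel.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$qc_detail, file.path(out_dir, "qc_log.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
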