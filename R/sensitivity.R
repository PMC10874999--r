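#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (ratio_j - beta_ivw_fixed)^2)` with the IVW weights
#' `(beta_exp/se_out)^2`; under homogeneity Q is chi-squared with
#' `n_snp - 1` df (upper-tail p).
#'
#' @param insts An `mr_harmonized` tibble with at least 2 instruments.
#' @return A one-row tibble: `q`, `q_df`, `q_p`.
#' @export
cochran_q <- function(insts) {
  k <- nrow(insts)
  if (k < 2) {
    rlang::abort("Cochran's Q requires at least 2 instruments",
                 class = "mrpipe_domain_error")
  }
  rc <- ratio_components(insts)
  beta <- sum(rc$w * rc$ratio) / sum(rc$w)
  q <- sum(rc$w * (rc$ratio - beta)^2)
  tibble::tibble(q = q, q_df = k - 1L,
                 q_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

# leave-one-out IVW slopes from sufficient statistics, vectorised:
# theta_(-j) = (sum(num) - num_j) / (sum(w) - w_j)
loo_theta <- function(bx, by, sy) {
  w <- (bx / sy)^2
  num <- bx * by / sy^2
  (sum(num) - num) / (sum(w) - w)
}

#' MR-PRESSO: global heterogeneity, outlier and distortion tests
#'
#' Simulation-based residual-sum-of-squares test for horizontal
#' pleiotropy. For each instrument j the expected outcome effect is taken
#' from the leave-one-out IVW fit (`theta_(-j) * beta_exp_j`); the observed
#' RSS is compared against `n_sim` parametric simulations in which
#' `beta_exp*` is drawn around the observed exposure effects and
#' `beta_out*` around the leave-one-out expectations. The global p uses the
#' `(1 + k)/(n_sim + 1)` Monte-Carlo estimator (so it is floored at
#' `1/(n_sim + 1)`). Per-SNP outlier p-values compare each observed squared
#' residual with its simulated distribution and are Bonferroni-adjusted by
#' the instrument count; SNPs with adjusted p below `signif_threshold` are
#' flagged. When the global test is significant and outliers are flagged,
#' the IVW estimate is re-run without them (`corrected`) and a
#' permutation-style distortion p-value compares the observed
#' corrected-vs-raw shift with shifts from dropping random subsets of the
#' same size.
#'
#' @param insts An `mr_harmonized` tibble with at least 4 instruments.
#' @param n_sim Simulated datasets (default 1000).
#' @param signif_threshold Significance level for the global and
#'   (adjusted) outlier tests (default 0.05).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `mr_presso`: list with `global_rss`,
#'   `global_p`, `outliers` (tibble `snp_id`, `raw_p`, `adj_p`, `flagged`),
#'   `corrected` (an `mr_result`, or `NULL` when nothing was flagged),
#'   `distortion_p` (or `NULL`), `n_sim`, `signif_threshold`, `seed`.
#' @export
mr_presso <- function(insts, n_sim = 1000, signif_threshold = 0.05,
                      seed = NULL) {
  k <- nrow(insts)
  if (k < 4) {
    rlang::abort("MR-PRESSO requires at least 4 instruments",
                 class = "mrpipe_domain_error")
  }
  run <- function() {
    bx <- insts$beta_exp; by <- insts$beta_out
    sx <- insts$se_exp; sy <- insts$se_out
    th_loo <- loo_theta(bx, by, sy)
    resid_obs <- (by - th_loo * bx)^2
    rss_obs <- sum(resid_obs)

    # simulate under the no-pleiotropy model, k x n_sim matrices
    bx_star <- matrix(stats::rnorm(k * n_sim, bx, sx), nrow = k)
    by_star <- matrix(stats::rnorm(k * n_sim, th_loo * bx, sy), nrow = k)
    w_star <- (bx_star / sy)^2
    num_star <- bx_star * by_star / sy^2
    th_star <- sweep(-num_star, 2, colSums(num_star), "+") /
      sweep(-w_star, 2, colSums(w_star), "+")
    resid_star <- (by_star - th_star * bx_star)^2
    rss_star <- colSums(resid_star)

    global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    raw_p <- (1 + rowSums(resid_star >= resid_obs)) / (n_sim + 1)
    adj_p <- pmin(1, raw_p * k)
    flagged <- adj_p < signif_threshold

    corrected <- NULL
    distortion_p <- NULL
    if (global_p < signif_threshold && any(flagged) && sum(!flagged) >= 2) {
      corrected <- mr_ivw(insts[!flagged, , drop = FALSE], model = "random")
      theta_all <- sum((bx / sy)^2 * (by / bx)) / sum((bx / sy)^2)
      d_obs <- (corrected$beta - theta_all) / abs(theta_all)
      m <- sum(flagged)
      d_star <- numeric(n_sim)
      for (b in seq_len(n_sim)) {
        drop <- sample.int(k, m)
        keep_bx <- bx[-drop]; keep_by <- by[-drop]; keep_sy <- sy[-drop]
        w2 <- (keep_bx / keep_sy)^2
        d_star[b] <- (sum(w2 * keep_by / keep_bx) / sum(w2) - theta_all) /
          abs(theta_all)
      }
      distortion_p <- (1 + sum(abs(d_star) >= abs(d_obs))) / (n_sim + 1)
    }
    list(global_rss = rss_obs, global_p = global_p,
         outliers = tibble::tibble(snp_id = insts$snp_id, raw_p = raw_p,
                                   adj_p = adj_p, flagged = flagged),
         corrected = corrected, distortion_p = distortion_p,
         n_sim = n_sim, signif_threshold = signif_threshold, seed = seed)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  n_flag <- sum(x$outliers$flagged)
  if (n_flag > 0) {
    cat(sprintf("  %d outlier(s): %s\n", n_flag,
                paste(x$outliers$snp_id[x$outliers$flagged], collapse = ", ")))
    if (!is.null(x$corrected)) {
      cat(sprintf("  corrected IVW beta = %.4g (p = %.3g)",
                  x$corrected$beta, x$corrected$pval))
      if (!is.null(x$distortion_p)) cat(sprintf(", distortion p = %.3g", x$distortion_p))
      cat("\n")
    }
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' @rdname mr_presso
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outliers

#' Leave-one-out analysis
#'
#' Recomputes the random-effects IVW estimate excluding each instrument in
#' turn; a single influential SNP shows up as a row whose estimate departs
#' from the rest.
#'
#' @param insts An `mr_harmonized` tibble with at least 2 instruments.
#' @return A tibble with one row per excluded SNP: `snp_id_excluded`,
#'   `n_snp`, `beta`, `se`, `pval`, `ci_low`, `ci_high` (odds-ratio scale
#'   CI).
#' @export
leave_one_out <- function(insts) {
  k <- nrow(insts)
  if (k < 2) {
    rlang::abort("leave-one-out requires at least 2 instruments",
                 class = "mrpipe_domain_error")
  }
  rows <- purrr::map(seq_len(k), function(j) {
    res <- suppressWarnings(mr_ivw(insts[-j, , drop = FALSE], model = "random"))
    tibble::tibble(snp_id_excluded = insts$snp_id[j],
                   n_snp = as.integer(res$n_snp), beta = res$beta,
                   se = res$se, pval = res$pval,
                   ci_low = res$ci_low, ci_high = res$ci_high)
  })
  dplyr::bind_rows(rows)
}

#' Funnel-plot data
#'
#' Per-instrument ratio estimates against their precision (1/SE of the
#' ratio); asymmetry around the pooled estimate suggests directional
#' pleiotropy.
#'
#' @param insts An `mr_harmonized` tibble (may be empty).
#' @return A tibble: `snp_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(insts) {
  if (nrow(insts) == 0) {
    return(tibble::tibble(snp_id = character(), ratio = double(),
                          precision = double()))
  }
  rc <- ratio_components(insts)
  tibble::tibble(snp_id = insts$snp_id, ratio = rc$ratio,
                 precision = 1 / rc$se)
}

#' Full sensitivity report
#'
#' Bundles every robustness diagnostic for one harmonized instrument set:
#' Cochran's Q, the MR-Egger intercept test, MR-PRESSO (when at least 4
#' instruments are available), leave-one-out, and funnel-plot data.
#' Diagnostics whose instrument-count minimum is not met are recorded as
#' skipped rather than aborting the report.
#'
#' @param insts An `mr_harmonized` tibble.
#' @param presso_n_sim,presso_threshold,seed Passed to [mr_presso()].
#' @return An object of class `mr_sensitivity`: list with `q` (tibble),
#'   `egger` (`mr_result` or `NULL`), `presso` (`mr_presso` or `NULL`),
#'   `loo`, `funnel`, and `skipped` (named character vector of skip
#'   reasons). `tidy()` flattens it to the one-row table-2-style summary.
#' @export
sensitivity_report <- function(insts, presso_n_sim = 1000,
                               presso_threshold = 0.05, seed = NULL) {
  skipped <- character()
  q <- if (nrow(insts) >= 2) cochran_q(insts) else {
    skipped["cochran_q"] <- "skipped: minimum 2 instruments"
    NULL
  }
  egger <- if (nrow(insts) >= 3) mr_egger(insts) else {
    skipped["egger"] <- "skipped: minimum 3 instruments"
    NULL
  }
  presso <- if (nrow(insts) >= 4) {
    mr_presso(insts, n_sim = presso_n_sim,
              signif_threshold = presso_threshold, seed = seed)
  } else {
    skipped["mr_presso"] <- "skipped: minimum 4 instruments"
    NULL
  }
  loo <- if (nrow(insts) >= 2) leave_one_out(insts) else NULL
  structure(list(q = q, egger = egger, presso = presso, loo = loo,
                 funnel = funnel_data(insts), skipped = skipped),
            class = "mr_sensitivity")
}

#' @rdname sensitivity_report
#' @param x An `mr_sensitivity` object.
#' @param ... Unused.
#' @method tidy mr_sensitivity
#' @export
tidy.mr_sensitivity <- function(x, ...) {
  corrected_p <- NA_real_
  if (!is.null(x$presso) && !is.null(x$presso$corrected)) {
    corrected_p <- x$presso$corrected$pval
  }
  tibble::tibble(
    egger_intercept = if (is.null(x$egger)) NA_real_ else x$egger$extra$egger_intercept,
    egger_intercept_p = if (is.null(x$egger)) NA_real_ else x$egger$extra$egger_intercept_p,
    q = if (is.null(x$q)) NA_real_ else x$q$q,
    q_p = if (is.null(x$q)) NA_real_ else x$q$q_p,
    presso_global_p = if (is.null(x$presso)) NA_real_ else x$presso$global_p,
    presso_corrected_p = corrected_p,
    presso_n_outliers = if (is.null(x$presso)) NA_integer_ else
      as.integer(sum(x$presso$outliers$flagged)))
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("<mr_sensitivity>\n")
  print(tidy(x))
  if (length(x$skipped) > 0) {
    for (nm in names(x$skipped)) cat(sprintf("  %s: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}
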