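#' Per-SNP variance explained
#'
#' Default formula `r2 = F / (F + n - 2)` with `F = (beta/se)^2`, which
#' needs no allele frequency and applies to binary-trait summary
#' statistics on the observed scale. For continuous traits with known
#' effect-allele frequency the standardized-scale alternative
#' `2 * eaf * (1 - eaf) * beta^2` can be selected.
#'
#' @param beta,se Effect estimate(s) and SE(s).
#' @param n GWAS sample size(s), > 2.
#' @param eaf Effect-allele frequency, required for `method = "eaf"`.
#' @param method `"fstat"` (default) or `"eaf"`.
#' @return Numeric vector of per-SNP r-squared values.
#' @export
snp_r2 <- function(beta, se, n, eaf = NULL, method = c("fstat", "eaf")) {
  method <- rlang::arg_match(method)
  if (method == "eaf") {
    if (is.null(eaf) || anyNA(eaf)) {
      rlang::abort("eaf required for the standardized-scale r2 formula")
    }
    return(2 * eaf * (1 - eaf) * beta^2)
  }
  if (any(!is.finite(n) | n <= 2)) {
    rlang::abort("sample size must exceed 2", class = "mrpipe_domain_error")
  }
  f <- f_statistic(beta, se)
  f / (f + n - 2)
}

#' Steiger directionality test
#'
#' Checks that the instruments explain more variance in the exposure than
#' in the outcome, as expected when causation runs exposure -> outcome.
#' Summed per-SNP r-squared values on each side are compared via Fisher's
#' z transform of the multiple correlations, with the two GWAS treated as
#' non-overlapping samples:
#' `z = (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
#'      sqrt(1/(n_exp - 3) + 1/(n_out - 3))`.
#'
#' @param insts An `mr_harmonized` tibble.
#' @param n_exp,n_out Scalar GWAS sample sizes. When omitted, taken from
#'   the instruments' `n_exp`/`n_out` columns (median when per-SNP values
#'   vary).
#' @return An object of class `mr_steiger`: list with `r2_exposure`,
#'   `r2_outcome`, `correct_direction` (strict `r2_exposure >
#'   r2_outcome`), `steiger_z`, `steiger_p` (two-sided), `n_exp`, `n_out`.
#' @export
steiger_test <- function(insts, n_exp = NULL, n_out = NULL) {
  if (nrow(insts) < 1) rlang::abort("at least one instrument required")
  n_exp <- n_exp %||% stats::median(insts$n_exp)
  n_out <- n_out %||% stats::median(insts$n_out)
  if (is.null(n_exp) || is.null(n_out) || anyNA(c(n_exp, n_out))) {
    rlang::abort(paste("GWAS sample sizes unknown; supply n_exp/n_out or set",
                       "n_default on the input datasets"),
                 class = "mrpipe_config_error")
  }
  r2_exp <- sum(snp_r2(insts$beta_exp, insts$se_exp, n_exp))
  r2_out <- sum(snp_r2(insts$beta_out, insts$se_out, n_out))
  z <- (atanh(sqrt(min(r2_exp, 1 - 1e-12))) -
          atanh(sqrt(min(r2_out, 1 - 1e-12)))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out,
                 correct_direction = r2_exp > r2_out,
                 steiger_z = z,
                 steiger_p = 2 * stats::pnorm(-abs(z)),
                 n_exp = n_exp, n_out = n_out),
            class = "mr_steiger")
}

#' @rdname steiger_test
#' @param x An `mr_steiger` object.
#' @param ... Unused.
#' @method tidy mr_steiger
#' @export
tidy.mr_steiger <- function(x, ...) {
  tibble::tibble(r2_exposure = x$r2_exposure, r2_outcome = x$r2_outcome,
                 correct_direction = x$correct_direction,
                 steiger_z = x$steiger_z, steiger_p = x$steiger_p)
}

#' @export
print.mr_steiger <- function(x, ...) {
  cat(sprintf("<mr_steiger> r2 exposure = %.4g, r2 outcome = %.4g\n",
              x$r2_exposure, x$r2_outcome))
  cat(sprintf("  direction %s, p = %.3g\n",
              if (x$correct_direction) "exposure -> outcome" else "NOT confirmed",
              x$steiger_p))
  invisible(x)
}
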