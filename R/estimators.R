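Z95 <- 1.959964

new_mr_result <- function(method, n_snp, beta, se, pval, extra = list()) {
  ci <- to_odds_ratio(beta, se)
  structure(list(method = method, n_snp = n_snp, beta = beta, se = se,
                 pval = pval, or_ = ci$or_, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, extra = extra),
            class = "mr_result")
}

#' Convert a log-scale estimate to an odds ratio with a 95 percent CI
#'
#' @param beta Log-odds causal estimate.
#' @param se Its standard error.
#' @return A list with `or_ = exp(beta)`, `ci_low = exp(beta - 1.959964
#'   se)` and `ci_high = exp(beta + 1.959964 se)`.
#' @export
to_odds_ratio <- function(beta, se) {
  list(or_ = exp(beta),
       ci_low = exp(beta - Z95 * se),
       ci_high = exp(beta + Z95 * se))
}

# per-SNP ratio estimates and the IVW weights (beta_exp/se_out)^2
ratio_components <- function(insts) {
  if (any(insts$beta_exp == 0)) {
    rlang::abort("beta_exp must be nonzero for ratio estimates",
                 class = "mrpipe_domain_error")
  }
  list(ratio = insts$beta_out / insts$beta_exp,
       se = insts$se_out / abs(insts$beta_exp),
       w = (insts$beta_exp / insts$se_out)^2)
}

#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate: outcome effect divided by
#' exposure effect, with first-order delta-method standard error
#' `se_out / |beta_exp|`.
#'
#' @param insts An `mr_harmonized` tibble (or any data frame with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @return A tibble with one row per instrument: `snp_id`, `beta`, `se`,
#'   `pval`, `or_`, `ci_low`, `ci_high`.
#' @export
wald_ratio <- function(insts) {
  rc <- ratio_components(insts)
  ci <- to_odds_ratio(rc$ratio, rc$se)
  tibble::tibble(snp_id = insts$snp_id, beta = rc$ratio, se = rc$se,
                 pval = 2 * stats::pnorm(-abs(rc$ratio / rc$se)),
                 or_ = ci$or_, ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted average of per-SNP Wald ratios with weights
#' `(beta_exp / se_out)^2` (equivalently a weights-`1/se_out^2` regression
#' of `beta_out` on `beta_exp` through the origin). The fixed-effect SE is
#' `1/sqrt(sum(w))`; the multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q / (n_snp - 1)))` where Q is Cochran's heterogeneity
#' statistic — it never deflates. P-values are two-sided normal.
#'
#' @param insts An `mr_harmonized` tibble.
#' @param model `"random"` (default, matching common reporting practice)
#'   or `"fixed"`. A single instrument falls back to fixed with a warning.
#' @return An `mr_result`; `extra` carries `q`, `q_df` and the model used.
#' @export
mr_ivw <- function(insts, model = c("random", "fixed")) {
  model <- rlang::arg_match(model)
  k <- nrow(insts)
  if (k == 0) rlang::abort("at least one instrument required")
  rc <- ratio_components(insts)
  beta <- sum(rc$w * rc$ratio) / sum(rc$w)
  se_fixed <- 1 / sqrt(sum(rc$w))
  q <- sum(rc$w * (rc$ratio - beta)^2)
  used <- model
  if (model == "random" && k == 1) {
    rlang::warn("random-effects IVW needs >= 2 instruments; falling back to fixed")
    used <- "fixed"
  }
  se <- if (used == "random") se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_result(if (used == "random") "ivw_re" else "ivw_fe",
                k, beta, se, pval,
                extra = list(q = q, q_df = k - 1, model = used))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects WITH
#' an intercept (weights `1/se_out^2`). The slope is the causal estimate;
#' a nonzero intercept indicates directional horizontal pleiotropy. Because
#' the fit is not invariant to allele coding, each instrument is first
#' oriented so that `beta_exp >= 0` (both effects sign-flipped when
#' needed); the stored instruments are never mutated. Standard errors use a
#' multiplicative overdispersion factor `max(1, weighted RSS / (n_snp -
#' 2))`; p-values are two-sided t with `n_snp - 2` df.
#'
#' @param insts An `mr_harmonized` tibble with at least 3 instruments.
#' @return An `mr_result`; `extra` carries `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p` and the overdispersion
#'   `sigma2`.
#' @export
mr_egger <- function(insts) {
  k <- nrow(insts)
  if (k < 3) {
    rlang::abort("MR-Egger requires at least 3 instruments",
                 class = "mrpipe_domain_error")
  }
  flip <- insts$beta_exp < 0
  bx <- ifelse(flip, -insts$beta_exp, insts$beta_exp)
  by <- ifelse(flip, -insts$beta_out, insts$beta_out)
  w <- 1 / insts$se_out^2

  X <- cbind(intercept = 1, slope = bx)
  xtw <- t(X * w)
  fit <- solve(xtw %*% X, xtw %*% by)
  resid <- by - X %*% fit
  rss_w <- sum(w * resid^2)
  sigma2 <- max(1, rss_w / (k - 2))
  vcov <- sigma2 * solve(xtw %*% X)
  se <- sqrt(diag(vcov))

  slope <- unname(fit["slope", 1])
  slope_se <- unname(se["slope"])
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df = k - 2)
  int <- unname(fit["intercept", 1])
  int_se <- unname(se["intercept"])
  int_p <- 2 * stats::pt(-abs(int / int_se), df = k - 2)
  new_mr_result("egger", k, slope, unname(slope_se), slope_p,
                extra = list(egger_intercept = int,
                             egger_intercept_se = unname(int_se),
                             egger_intercept_p = int_p,
                             sigma2 = sigma2))
}

# cumulative-midpoint weighted median of ratio estimates
weighted_median_core <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, ratio, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP ratio estimates and interpolates the weighted median
#' (normalized inverse-variance weights, cumulative midpoints). Consistent
#' when at least half the total weight comes from valid instruments. The
#' standard error is the standard deviation of the estimate over `n_boot`
#' parametric-bootstrap replicates, each perturbing `beta_exp` and
#' `beta_out` by independent normal noise with their reported SEs.
#'
#' @param insts An `mr_harmonized` tibble with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap; `NULL` uses the current RNG
#'   state.
#' @return An `mr_result`; `extra` carries `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(insts, n_boot = 1000, seed = NULL) {
  k <- nrow(insts)
  if (k < 3) {
    rlang::abort("weighted median requires at least 3 instruments",
                 class = "mrpipe_domain_error")
  }
  rc <- ratio_components(insts)
  est <- weighted_median_core(rc$ratio, rc$w)
  boot_fun <- function() {
    reps <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bx <- stats::rnorm(k, insts$beta_exp, insts$se_exp)
      by <- stats::rnorm(k, insts$beta_out, insts$se_out)
      bx[bx == 0] <- .Machine$double.eps
      reps[b] <- weighted_median_core(by / bx, (bx / insts$se_out)^2)
    }
    reps
  }
  reps <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
  se <- stats::sd(reps)
  pval <- 2 * stats::pnorm(-abs(est / se))
  new_mr_result("weighted_median", k, est, se, pval,
                extra = list(n_boot = n_boot, seed = seed))
}

#' Run a panel of MR estimators
#'
#' Applies the requested estimators to one harmonized instrument set and
#' row-binds their tidied results. Methods whose instrument-count minimum
#' is not met are skipped with a message and recorded in the `skipped`
#' attribute rather than aborting the panel.
#'
#' @param insts An `mr_harmonized` tibble.
#' @param methods Subset of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @param model IVW variant, `"random"` or `"fixed"`.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return A tibble with columns `method`, `n_snp`, `beta`, `se`, `pval`,
#'   `or_`, `ci_low`, `ci_high` — one row per method run.
#' @export
mr_estimate <- function(insts, methods = c("ivw", "egger", "weighted_median"),
                        model = "random", n_boot = 1000, seed = NULL) {
  if (length(methods) > 0) {
    methods <- match.arg(methods, c("ivw", "egger", "weighted_median"),
                         several.ok = TRUE)
  }
  minimum <- c(ivw = 1, egger = 3, weighted_median = 3)
  skipped <- character()
  rows <- list()
  for (m in methods) {
    if (nrow(insts) < minimum[[m]]) {
      msg <- sprintf("skipped: minimum %d instruments", minimum[[m]])
      skipped[m] <- msg
      message(sprintf("%s %s", m, msg))
      next
    }
    res <- switch(m,
                  ivw = mr_ivw(insts, model = model),
                  egger = mr_egger(insts),
                  weighted_median = mr_weighted_median(insts, n_boot = n_boot,
                                                       seed = seed))
    rows[[m]] <- tidy(res)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(method = character(), n_snp = integer(),
                          beta = double(), se = double(), pval = double(),
                          or_ = double(), ci_low = double(), ci_high = double())
  }
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s, %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4g (se %.4g), OR = %.4g (%.4g, %.4g), p = %.3g\n",
              x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval))
  if (x$method == "egger") {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$extra$egger_intercept, x$extra$egger_intercept_se,
                x$extra$egger_intercept_p))
  }
  invisible(x)
}

#' @describeIn mr_estimate Tidy a single `mr_result` into a one-row tibble.
#' @param x An `mr_result`.
#' @param ... Unused.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = as.integer(x$n_snp),
                 beta = x$beta, se = x$se, pval = x$pval,
                 or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @describeIn mr_estimate One-row model summary including method-specific
#'   extras (Egger intercept, heterogeneity Q).
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  base <- tidy(x)
  extras <- x$extra[!vapply(x$extra, is.null, logical(1))]
  extras <- extras[vapply(extras, function(v) is.numeric(v) && length(v) == 1,
                          logical(1))]
  if (length(extras) > 0) base <- dplyr::bind_cols(base, tibble::as_tibble(extras))
  base
}
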