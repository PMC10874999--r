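#' Configure a synthetic two-sample GWAS study
#'
#' Builds the parameter set for [simulate_study()]. The generator follows a
#' linear instrumental-variable model: each SNP j has a true exposure
#' effect `gamma_j`, an optional direct (pleiotropic) outcome effect
#' `alpha_j`, and a true outcome association `Gamma_j = theta * gamma_j +
#' alpha_j`. Per-SNP standard errors use the standard GWAS approximation
#' `se = 1 / sqrt(2 * maf * (1 - maf) * n)`, and observed effects are
#' drawn normally around the truth. Defaults emulate a well-powered
#' biobank-scale pair of GWAS (sample sizes of the order used for common
#' binary traits and disease endpoints) with strong instruments.
#'
#' @param n_snp Number of instruments to generate.
#' @param theta True causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd Normal distribution of true exposure effects.
#' @param gamma_min Lower truncation for the true exposure effect:
#'   instruments are coded to the exposure-increasing allele (the field's
#'   orientation convention) and emulate hits that passed the
#'   genome-wide-significance screen, so effects are bounded away from
#'   zero. The
#'   truncation also keeps the exposure-effect spread large relative to
#'   its estimation error, the condition (no measurement error, NOME)
#'   under which the MR-Egger intercept is an unbiased estimate of mean
#'   pleiotropy.
#' @param pleiotropy `"none"`, `"balanced"` (alpha ~ N(0, sd)) or
#'   `"directional"` (alpha ~ N(mean, sd)).
#' @param pleiotropy_mean,pleiotropy_sd Parameters of the pleiotropy
#'   regime.
#' @param n_exp,n_out GWAS sample sizes for the exposure and outcome.
#' @param maf_range Uniform range for minor-allele frequencies, within
#'   (0, 0.5].
#' @param n_outlier Number of planted outlier SNPs.
#' @param outlier_offset Outlier shift in units of the SNP's outcome SE.
#' @param frac_swap,frac_flip,frac_duplicate Fractions of OUTCOME records
#'   to allele-swap (beta negated, eaf reflected — recoverable by
#'   harmonization), strand-flip (alleles complemented, effects
#'   unchanged), or duplicate.
#' @param frac_palindromic Fraction of SNPs given an A/T or C/G allele
#'   pair. A palindrome is a property of the variant, so these allele
#'   pairs appear in both files.
#' @param reverse Swap the causal roles: the file served as "exposure"
#'   carries the downstream trait (used to test directionality).
#' @param seed Master seed; drives stream-split sub-seeds for effects,
#'   sampling noise, and allele edits.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_snp = 80, theta = 0.5,
                              gamma_mean = 0.2, gamma_sd = 0.1,
                              gamma_min = 0.05,
                              pleiotropy = c("none", "balanced", "directional"),
                              pleiotropy_mean = 0.02, pleiotropy_sd = 0.01,
                              n_exp = 337159, n_out = 216362,
                              maf_range = c(0.05, 0.45),
                              n_outlier = 0, outlier_offset = 10,
                              frac_swap = 0, frac_flip = 0,
                              frac_palindromic = 0, frac_duplicate = 0,
                              reverse = FALSE, seed = 1L) {
  pleiotropy <- rlang::arg_match(pleiotropy)
  cfg <- list(n_snp = n_snp, theta = theta, gamma_mean = gamma_mean,
              gamma_sd = gamma_sd, gamma_min = gamma_min,
              pleiotropy = pleiotropy,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              n_exp = n_exp, n_out = n_out, maf_range = maf_range,
              n_outlier = n_outlier, outlier_offset = outlier_offset,
              frac_swap = frac_swap, frac_flip = frac_flip,
              frac_palindromic = frac_palindromic,
              frac_duplicate = frac_duplicate, reverse = reverse,
              seed = as.integer(seed))
  if (n_snp < 1) rlang::abort("n_snp must be >= 1")
  if (gamma_min < 0) rlang::abort("gamma_min must be >= 0")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    rlang::abort("maf_range must lie within (0, 0.5]")
  }
  fr <- c(frac_swap, frac_flip, frac_palindromic, frac_duplicate)
  if (any(fr < 0 | fr > 1)) rlang::abort("fractions must lie in [0, 1]")
  if (n_outlier > n_snp) {
    rlang::abort("more planted outliers than SNPs", class = "mrpipe_config_error")
  }
  structure(cfg, class = "sim_config")
}

NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome summary-statistics study
#'
#' Generates two `mr_sumstats` datasets under the model described in
#' [simulation_config()], together with the ground truth against which
#' estimator recovery can be tested. All randomness comes from the
#' config's single master seed (same seed, byte-identical output);
#' harmonization noise (allele swaps, strand flips, duplicates) is applied
#' to the outcome file only, so exposure-side instrument selection is
#' undisturbed. Truth is recorded before sampling noise is added.
#'
#' @param config A [simulation_config()] (or a scenario preset from
#'   [mr_scenario()]).
#' @return A list with elements `exposure`, `outcome` (both
#'   `mr_sumstats`) and `truth` (class `sim_truth`: `theta`, per-SNP
#'   tibble `snps` with `gamma`, `alpha`, flags for planted outliers,
#'   palindromes and edits, plus the seed and config).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_snp
  sub_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max - 1L, 3))

  # effects stream: truth and variant identities
  eff <- withr::with_seed(sub_seeds[1], {
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(k, config$gamma_mean, config$gamma_sd)
    # rejection-sample the truncation gamma >= gamma_min: instruments are
    # coded to the exposure-increasing allele and have passed the
    # significance screen, so true effects are positive and bounded away
    # from zero
    while (any(bad <- gamma < config$gamma_min)) {
      gamma[bad] <- stats::rnorm(sum(bad), config$gamma_mean, config$gamma_sd)
    }
    alpha <- switch(config$pleiotropy,
                    none = rep(0, k),
                    balanced = stats::rnorm(k, 0, config$pleiotropy_sd),
                    directional = stats::rnorm(k, config$pleiotropy_mean,
                                               config$pleiotropy_sd))
    n_pal <- round(config$frac_palindromic * k)
    pal_idx <- if (n_pal > 0) sample.int(k, n_pal) else integer()
    pair_idx <- sample.int(nrow(NONPAL_PAIRS), k, replace = TRUE)
    alleles <- NONPAL_PAIRS[pair_idx, , drop = FALSE]
    if (n_pal > 0) {
      alleles[pal_idx, ] <- PAL_PAIRS[sample.int(nrow(PAL_PAIRS), n_pal,
                                                 replace = TRUE), , drop = FALSE]
    }
    out_idx <- if (config$n_outlier > 0) sample.int(k, config$n_outlier) else integer()
    chrom <- sample(1:22, k, replace = TRUE)
    pos <- sample.int(2.5e8, k)
    list(maf = maf, gamma = gamma, alpha = alpha, pal_idx = pal_idx,
         alleles = alleles, out_idx = out_idx, chrom = chrom, pos = pos)
  })

  se_x <- 1 / sqrt(2 * eff$maf * (1 - eff$maf) * config$n_exp)
  se_y <- 1 / sqrt(2 * eff$maf * (1 - eff$maf) * config$n_out)
  big_gamma <- config$theta * eff$gamma + eff$alpha
  # the exposure file carries the trait instruments are selected on; under
  # reverse causation that is the downstream trait
  mu_x <- if (config$reverse) big_gamma else eff$gamma
  mu_y <- if (config$reverse) eff$gamma else big_gamma
  mu_y_shift <- mu_y
  mu_y_shift[eff$out_idx] <- mu_y[eff$out_idx] +
    config$outlier_offset * se_y[eff$out_idx]

  # noise stream: observed effects
  obs <- withr::with_seed(sub_seeds[2], {
    list(bx = stats::rnorm(k, mu_x, se_x),
         by = stats::rnorm(k, mu_y_shift, se_y))
  })
  # p-values exactly two-sided normal, floored at the smallest positive
  # double so extreme associations stay inside (0, 1]
  p_of <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)), .Machine$double.xmin)

  snp_id <- sprintf("rs%07d", seq_len(k))
  exposure <- tibble::tibble(
    snp_id = snp_id, chrom = as.character(eff$chrom), pos = eff$pos,
    effect_allele = eff$alleles[, 1], other_allele = eff$alleles[, 2],
    eaf = eff$maf, beta = obs$bx, se = se_x, pval = p_of(obs$bx, se_x),
    n = config$n_exp)
  outcome <- tibble::tibble(
    snp_id = snp_id, chrom = as.character(eff$chrom), pos = eff$pos,
    effect_allele = eff$alleles[, 1], other_allele = eff$alleles[, 2],
    eaf = eff$maf, beta = obs$by, se = se_y, pval = p_of(obs$by, se_y),
    n = config$n_out)

  # edits stream: harmonization noise on the outcome file only
  edits <- withr::with_seed(sub_seeds[3], {
    n_swap <- round(config$frac_swap * k)
    swap_idx <- if (n_swap > 0) sample.int(k, n_swap) else integer()
    flippable <- setdiff(which(!seq_len(k) %in% eff$pal_idx), swap_idx)
    n_flip <- min(round(config$frac_flip * k), length(flippable))
    flip_idx <- if (n_flip > 0) sample(flippable, n_flip) else integer()
    n_dup <- round(config$frac_duplicate * k)
    dup_idx <- if (n_dup > 0) sample.int(k, n_dup) else integer()
    list(swap = swap_idx, flip = flip_idx, dup = dup_idx)
  })
  if (length(edits$swap) > 0) {
    i <- edits$swap
    ea <- outcome$effect_allele[i]
    outcome$effect_allele[i] <- outcome$other_allele[i]
    outcome$other_allele[i] <- ea
    outcome$beta[i] <- -outcome$beta[i]
    outcome$eaf[i] <- 1 - outcome$eaf[i]
  }
  if (length(edits$flip) > 0) {
    i <- edits$flip
    outcome$effect_allele[i] <- complement_allele(outcome$effect_allele[i])
    outcome$other_allele[i] <- complement_allele(outcome$other_allele[i])
  }
  if (length(edits$dup) > 0) {
    outcome <- dplyr::bind_rows(outcome, outcome[edits$dup, , drop = FALSE])
  }

  truth <- structure(
    list(theta = config$theta,
         snps = tibble::tibble(
           snp_id = snp_id, maf = eff$maf, gamma = eff$gamma,
           alpha = eff$alpha,
           outlier = seq_len(k) %in% eff$out_idx,
           palindromic = seq_len(k) %in% eff$pal_idx,
           swapped = seq_len(k) %in% edits$swap,
           flipped = seq_len(k) %in% edits$flip,
           duplicated = seq_len(k) %in% edits$dup),
         seed = config$seed, reverse = config$reverse, config = config),
    class = "sim_truth")

  list(exposure = as_sumstats(exposure, trait_label = "exposure",
                              trait_type = "binary", n_default = config$n_exp),
       outcome = as_sumstats(outcome, trait_label = "outcome",
                             trait_type = "binary", n_default = config$n_out),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> theta = %g, %d SNP(s), seed %d%s\n",
              x$theta, nrow(x$snps), x$seed,
              if (x$reverse) " (reverse causation)" else ""))
  invisible(x)
}

#' Preset simulation scenarios
#'
#' Documented study conditions used throughout the test suite:
#' \describe{
#'   \item{null}{No causal effect, no pleiotropy (type-I calibration).}
#'   \item{causal}{theta = 0.5 with 80 strong instruments (parameter
#'     recovery and CI coverage).}
#'   \item{directional_pleiotropy}{theta = 0.5 plus a directional direct
#'     effect alpha ~ N(0.02, 0.01) on every SNP (Egger intercept
#'     detection).}
#'   \item{outlier}{theta = 0.5, 10 instruments, one planted outlier
#'     shifted 10 outcome-SEs (MR-PRESSO machinery). The small panel keeps
#'     the Bonferroni-adjusted per-SNP p-value floor below the 0.05
#'     flagging threshold at moderate simulation counts.}
#'   \item{reverse}{True causation runs outcome -> exposure (Steiger
#'     directionality).}
#' }
#'
#' @param name Scenario name.
#' @param seed Master seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
mr_scenario <- function(name = c("null", "causal", "directional_pleiotropy",
                                 "outlier", "reverse"), seed = 1L, ...) {
  name <- rlang::arg_match(name)
  preset <- switch(name,
    null = list(theta = 0, pleiotropy = "none"),
    causal = list(theta = 0.5),
    directional_pleiotropy = list(theta = 0.5, pleiotropy = "directional",
                                  pleiotropy_mean = 0.02, pleiotropy_sd = 0.01),
    outlier = list(theta = 0.5, n_snp = 10, n_outlier = 1, outlier_offset = 10),
    reverse = list(theta = 0.5, reverse = TRUE))
  args <- utils::modifyList(preset, list(...))
  args$seed <- seed
  do.call(simulation_config, args)
}
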