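# shared fixtures and independent oracles

# build a harmonized-instrument table directly from effect vectors
make_insts <- function(beta_exp, beta_out, se_out,
                       se_exp = rep(0.01, length(beta_exp)),
                       snp_id = sprintf("rs%03d", seq_along(beta_exp)),
                       n_exp = 50000, n_out = 50000) {
  tibble::tibble(snp_id = snp_id,
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out,
                 n_exp = n_exp, n_out = n_out)
}

# hand-computed 3-instrument set: ratios 0.5/0.6/0.4, IVW weights 100/25/25
fixture3 <- function() {
  make_insts(beta_exp = c(0.5, 0.4, 0.25),
             beta_out = c(0.25, 0.24, 0.10),
             se_out = c(0.05, 0.08, 0.05))
}

# weighted-least-squares-through-origin oracle for fixed-effect IVW
ivw_origin_oracle <- function(insts) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = insts,
                   weights = 1 / insts$se_out^2)
  unname(stats::coef(fit))
}

# brute-force cumulative-weight interpolation oracle for the weighted median
wm_oracle <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(ratio[1])
  if (0.5 >= s[length(s)]) return(ratio[length(s)])
  i <- max(which(s <= 0.5))
  ratio[i] + (ratio[i + 1] - ratio[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# exhaustive greedy clumping oracle over explicit pairwise tables
clump_oracle <- function(df, r2_mat, window_kb, r2_max) {
  kept <- character()
  remaining <- seq_len(nrow(df))
  while (length(remaining) > 0) {
    sub <- df[remaining, ]
    o <- order(sub$pval, ifelse(is.na(sub$pos), Inf, sub$pos), sub$snp_id)
    idx <- remaining[o[1]]
    kept <- c(kept, df$snp_id[idx])
    drop <- vapply(remaining, function(j) {
      if (j == idx) return(TRUE)
      same_chr <- df$chrom[j] == df$chrom[idx]
      within <- abs(df$pos[j] - df$pos[idx]) <= window_kb * 1000
      same_chr && within && r2_mat[df$snp_id[j], df$snp_id[idx]] > r2_max
    }, logical(1))
    remaining <- remaining[!drop]
  }
  kept
}

# two-sided normal p implied by an effect and its SE
consistent_p <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
}

# random non-palindromic sumstats table for io/selection tests
random_sumstats <- function(k, seed = 1) {
  withr::with_seed(seed, {
    beta <- rnorm(k, 0, 0.05)
    se <- runif(k, 0.02, 0.05)
    tibble::tibble(
      snp_id = sprintf("rs%04d", sample.int(9999, k)),
      chrom = as.character(sample(1:3, k, replace = TRUE)),
      pos = sample.int(1e7, k),
      effect_allele = ea <- sample(c("A", "C"), k, replace = TRUE),
      other_allele = ifelse(ea == "A", "G", "T"),
      eaf = runif(k, 0.05, 0.95),
      beta = beta, se = se,
      pval = consistent_p(beta, se))
  })
}

# one simulated, harmonized instrument set for a scenario
sim_insts <- function(name, seed, ...) {
  sim <- simulate_study(mr_scenario(name, seed = seed, ...))
  harmonize(sim$exposure, sim$outcome)
}
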