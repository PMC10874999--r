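test_that("significance screen is strict at the threshold", {
  df <- random_sumstats(3)
  df$pval <- c(1e-9, 5e-8, 1e-7)
  df$se <- 0.01
  df$beta <- -qnorm(df$pval / 2) * df$se
  ds <- as_sumstats(df)
  out <- select_by_pvalue(ds, 5e-8)
  expect_equal(nrow(out), 1)
  expect_equal(out$pval, 1e-9)
  log <- qc_log(out)
  expect_equal(sum(log$disposition == "dropped_pvalue"), 2)

  df$pval <- rep(1e-10, 3)
  df$beta <- -qnorm(df$pval / 2) * df$se
  expect_equal(nrow(select_by_pvalue(as_sumstats(df), 5e-8)), 3)

  df$pval <- rep(0.5, 3)
  df$beta <- -qnorm(df$pval / 2) * df$se
  expect_warning(none <- select_by_pvalue(as_sumstats(df), 5e-8), "no records")
  expect_equal(nrow(none), 0)
})

clump_fixture <- function() {
  as_sumstats(tibble::tibble(
    snp_id = c("rsA", "rsB", "rsC"),
    chrom = "1", pos = c(1e6, 1e6 + 50e3, 1e6 + 200e3),
    effect_allele = "A", other_allele = "G",
    beta = -qnorm(c(1e-20, 1e-15, 1e-9) / 2) * 0.01,
    se = 0.01, pval = c(1e-20, 1e-15, 1e-9)))
}

clump_ld <- function() {
  ld_table(tibble::tibble(snp_a = c("rsA", "rsA", "rsB"),
                          snp_b = c("rsB", "rsC", "rsC"),
                          r2 = c(0.5, 0.0005, 0.0004)))
}

test_that("greedy clumping keeps independent index SNPs and logs the culprit", {
  out <- greedy_clump(clump_fixture(), clump_ld(), window_kb = 10000,
                      r2_max = 0.001)
  expect_setequal(out$snp_id, c("rsA", "rsC"))
  log <- qc_log(out)
  b <- log[log$snp_id == "rsB", ]
  expect_equal(b$disposition, "dropped_clump")
  expect_equal(b$index_snp, "rsA")
})

test_that("unlinked SNPs are all retained", {
  out <- greedy_clump(clump_fixture(), ld = NULL)
  expect_equal(nrow(out), 3)
})

test_that("equal p-values in one clump resolve by position then id", {
  ds <- as_sumstats(tibble::tibble(
    snp_id = c("rsZ", "rsY"), chrom = "1", pos = c(2e6, 1e6),
    effect_allele = "A", other_allele = "G",
    beta = -qnorm(1e-10 / 2) * 0.01, se = 0.01, pval = 1e-10))
  ld <- ld_table(tibble::tibble(snp_a = "rsZ", snp_b = "rsY", r2 = 0.9))
  out <- greedy_clump(ds, ld)
  expect_equal(out$snp_id, "rsY")  # smaller position wins
})

test_that("records without coordinates fall back to LD-only clumping with a warning", {
  ds <- as_sumstats(tibble::tibble(
    snp_id = c("rs1", "rs2"),
    effect_allele = "A", other_allele = "G",
    beta = -qnorm(c(1e-10, 1e-9) / 2) * 0.01,
    se = 0.01, pval = c(1e-10, 1e-9)))
  ld <- ld_table(tibble::tibble(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  expect_warning(out <- greedy_clump(ds, ld), "LD-only")
  expect_equal(out$snp_id, "rs1")
})

test_that("greedy clumping agrees with the exhaustive oracle on random instances", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      k <- sample(3:12, 1)
      ids <- sprintf("rs%02d", 1:k)
      df <- tibble::tibble(
        snp_id = ids, chrom = as.character(sample(1:2, k, replace = TRUE)),
        pos = sample.int(3e7, k),
        effect_allele = "A", other_allele = "G",
        se = 0.01,
        pval = 10^runif(k, -30, -8))
      df$beta <- -qnorm(df$pval / 2) * df$se
      pairs <- t(combn(ids, 2))
      r2 <- ifelse(runif(nrow(pairs)) < 0.4, runif(nrow(pairs)), 0)
      ld <- ld_table(tibble::tibble(snp_a = pairs[, 1], snp_b = pairs[, 2],
                                    r2 = r2))
      r2_mat <- matrix(0, k, k, dimnames = list(ids, ids))
      for (i in seq_len(nrow(pairs))) {
        r2_mat[pairs[i, 1], pairs[i, 2]] <- r2[i]
        r2_mat[pairs[i, 2], pairs[i, 1]] <- r2[i]
      }
      window <- sample(c(100, 5000, 10000), 1)
      out <- greedy_clump(as_sumstats(df), ld, window_kb = window,
                          r2_max = 0.001)
      expect_equal(sort(out$snp_id),
                   sort(clump_oracle(df, r2_mat, window, 0.001)))
    })
  }
})

test_that("F statistic follows beta^2/se^2 and rejects non-positive SEs", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.05), 0)
  expect_equal(f_statistic(0.03, 0.01), 9)
  expect_error(f_statistic(0.1, 0), class = "mrpipe_domain_error")
})

test_that("weak-instrument filter drops F < 10 and keeps F = 10 exactly", {
  df <- random_sumstats(3)
  df$beta <- c(0.1, 0.03, sqrt(10) * 0.01)
  df$se <- 0.01
  df$pval <- consistent_p(df$beta, df$se)
  out <- filter_weak(as_sumstats(df), f_min = 10)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$f_stat), sort(c(100, 10)))
  expect_equal(sum(qc_log(out)$disposition == "dropped_weak_F"), 1)

  all_strong <- random_sumstats(5, seed = 2)
  all_strong$beta <- 0.2; all_strong$se <- 0.01
  all_strong$pval <- consistent_p(all_strong$beta, all_strong$se)
  expect_equal(nrow(filter_weak(as_sumstats(all_strong))), 5)

  empty <- as_sumstats(random_sumstats(3)[0, ])
  expect_equal(nrow(filter_weak(empty)), 0)
})

test_that("blocklist exclusion removes exactly the listed SNPs", {
  ds <- as_sumstats(random_sumstats(5, seed = 3))
  expect_equal(nrow(apply_blocklist(ds, c("rs_none"))), 5)

  out <- apply_blocklist(ds, ds$snp_id[2])
  expect_equal(nrow(out), 4)
  expect_equal(sum(qc_log(out)$disposition == "dropped_blocklist"), 1)

  expect_warning(gone <- apply_blocklist(ds, ds$snp_id), "every record")
  expect_equal(nrow(gone), 0)
})

test_that("each stage's dispositions partition its input exactly", {
  ds <- as_sumstats(random_sumstats(30, seed = 4))
  for (stage in list(select_by_pvalue(ds, 0.5),
                     greedy_clump(ds),
                     filter_weak(ds, f_min = 5),
                     apply_blocklist(ds, ds$snp_id[1:3]))) {
    log <- qc_log(stage)
    expect_setequal(log$snp_id, ds$snp_id)
    expect_equal(sum(log$disposition == "retained"), nrow(stage))
    expect_true(all(stage$snp_id %in% ds$snp_id))
  }
})

test_that("clump and F filter commute when every instrument is strong", {
  withr::with_seed(5, {
    df <- random_sumstats(15)
    df$beta <- runif(15, 0.1, 0.3)
    df$se <- 0.01  # all F >= 100
    df$pval <- consistent_p(df$beta, df$se)
    ds <- as_sumstats(df)
    a <- filter_weak(greedy_clump(ds), f_min = 10)
    b <- greedy_clump(filter_weak(ds, f_min = 10))
    expect_setequal(a$snp_id, b$snp_id)
  })
})
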