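test_that("Wald ratio follows the delta-method formula, including signs", {
  one <- make_insts(0.5, 0.25, 0.05)
  w <- wald_ratio(one)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)

  expect_equal(wald_ratio(make_insts(0.5, 0, 0.05))$beta, 0)
  neg <- wald_ratio(make_insts(-0.5, 0.25, 0.05))
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, 0.1)
  expect_error(wald_ratio(make_insts(0, 0.1, 0.05)),
               class = "mrpipe_domain_error")
})

test_that("the hand-computed 3-instrument set gives IVW beta 0.5, se sqrt(1/150)", {
  fe <- mr_ivw(fixture3(), model = "fixed")
  expect_equal(fe$beta, 0.5, tolerance = 1e-12)
  expect_equal(fe$se, sqrt(1 / 150), tolerance = 1e-12)
  expect_equal(fe$extra$q, 0.5, tolerance = 1e-12)
})

test_that("a single instrument reduces IVW to the Wald ratio", {
  one <- make_insts(0.5, 0.25, 0.05)
  expect_warning(res <- mr_ivw(one, model = "random"), "falling back")
  w <- wald_ratio(one)
  expect_equal(res$beta, w$beta)
  expect_equal(res$se, w$se)
})

test_that("identical instruments give Q = 0 and random = fixed", {
  same <- make_insts(rep(0.4, 4), rep(0.2, 4), rep(0.05, 4))
  fe <- mr_ivw(same, model = "fixed")
  re <- mr_ivw(same, model = "random")
  expect_equal(fe$extra$q, 0)
  expect_equal(re$beta, 0.5)
  expect_equal(re$se, fe$se)
})

test_that("fixed-effect IVW matches the weighted regression-through-origin oracle", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      k <- sample(3:40, 1)
      insts <- make_insts(beta_exp = runif(k, 0.05, 0.5) * sample(c(-1, 1), k, TRUE),
                          beta_out = rnorm(k, 0.1, 0.1),
                          se_out = runif(k, 0.01, 0.2))
      expect_equal(mr_ivw(insts, model = "fixed")$beta,
                   ivw_origin_oracle(insts), tolerance = 1e-10)
    })
  }
})

test_that("random-effects se is never below fixed, equal when Q <= df", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      k <- sample(2:30, 1)
      insts <- make_insts(beta_exp = runif(k, 0.05, 0.5),
                          beta_out = rnorm(k, 0.05, 0.2),
                          se_out = runif(k, 0.01, 0.2))
      fe <- mr_ivw(insts, model = "fixed")
      re <- mr_ivw(insts, model = "random")
      expect_gte(re$se, fe$se)
      if (fe$extra$q <= k - 1) expect_equal(re$se, fe$se)
    })
  }
})

test_that("Egger matches the weighted-least-squares oracle on the hand fixture", {
  e <- mr_egger(fixture3())
  # frozen from an independent lm(by ~ bx, weights = 1/sy^2) fit
  expect_equal(e$beta, 0.6129870129870, tolerance = 1e-10)
  expect_equal(e$extra$egger_intercept, -0.0467532467532, tolerance = 1e-10)
  expect_error(mr_egger(fixture3()[1:2, ]), "3", class = "mrpipe_domain_error")
})

test_that("Egger coefficients equal lm's on random instances; SEs floored at sigma2 = 1", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      k <- sample(4:30, 1)
      insts <- make_insts(beta_exp = runif(k, 0.05, 0.5),
                          beta_out = rnorm(k, 0.1, 0.1),
                          se_out = runif(k, 0.01, 0.2))
      fit <- lm(beta_out ~ beta_exp, data = insts, weights = 1 / insts$se_out^2)
      e <- mr_egger(insts)
      expect_equal(e$beta, unname(coef(fit)[2]), tolerance = 1e-10)
      expect_equal(e$extra$egger_intercept, unname(coef(fit)[1]),
                   tolerance = 1e-10)
      # dispersion floor: package se >= lm-style se whenever lm's sigma2 < 1
      rss_w <- sum((1 / insts$se_out^2) * resid(fit)^2)
      if (rss_w / (k - 2) >= 1) {
        expect_equal(e$se, unname(summary(fit)$coefficients[2, 2]),
                     tolerance = 1e-8)
      } else {
        expect_gte(e$se, unname(summary(fit)$coefficients[2, 2]) - 1e-12)
      }
    })
  }
})

test_that("noise-free proportional instruments recover theta exactly with zero intercept", {
  withr::with_seed(3, {
    theta <- 0.37
    gamma <- runif(8, 0.1, 0.5)
    insts <- make_insts(gamma, theta * gamma, se_out = runif(8, 0.02, 0.1))
    e <- mr_egger(insts)
    expect_equal(e$beta, theta, tolerance = 1e-12)
    expect_equal(e$extra$egger_intercept, 0, tolerance = 1e-12)
  })
})

test_that("a constant added to all outcome effects shifts the intercept, not the slope", {
  withr::with_seed(4, {
    insts <- make_insts(runif(6, 0.1, 0.5), rnorm(6, 0.1, 0.05),
                        se_out = rep(0.05, 6))  # equal weights: exact property
    e0 <- mr_egger(insts)
    shifted <- insts
    shifted$beta_out <- shifted$beta_out + 0.3
    e1 <- mr_egger(shifted)
    expect_equal(e1$beta, e0$beta, tolerance = 1e-10)
    expect_equal(e1$extra$egger_intercept, e0$extra$egger_intercept + 0.3,
                 tolerance = 1e-10)
  })
})

test_that("the weighted median hits the middle ratio when cumulative weight crosses there", {
  wm <- mr_weighted_median(fixture3(), n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.5, tolerance = 1e-12)
  expect_error(mr_weighted_median(fixture3()[1:2, ], seed = 1),
               class = "mrpipe_domain_error")
})

test_that("equal weights interpolate between the central ratios", {
  # ratios {0.1, 0.2, 0.8, 0.9}: s = 1/2 lands midway between 0.2 and 0.8
  insts <- make_insts(beta_exp = rep(1, 4),
                      beta_out = c(0.1, 0.2, 0.8, 0.9),
                      se_out = rep(0.1, 4))
  wm <- mr_weighted_median(insts, n_boot = 100, seed = 2)
  expect_equal(wm$beta, 0.5, tolerance = 1e-12)
})

test_that("the weighted median equals the brute-force oracle on random instances", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      k <- sample(3:25, 1)
      insts <- make_insts(beta_exp = runif(k, 0.05, 0.5),
                          beta_out = rnorm(k, 0.1, 0.2),
                          se_out = runif(k, 0.01, 0.2))
      rc <- list(ratio = insts$beta_out / insts$beta_exp,
                 w = (insts$beta_exp / insts$se_out)^2)
      wm <- mr_weighted_median(insts, n_boot = 10, seed = seed)
      expect_equal(wm$beta, wm_oracle(rc$ratio, rc$w), tolerance = 1e-10)
      expect_gte(wm$beta, min(rc$ratio))
      expect_lte(wm$beta, max(rc$ratio))
    })
  }
})

test_that("identical ratios collapse the weighted median with a small bootstrap se", {
  insts <- make_insts(rep(0.5, 5), rep(0.15, 5), rep(0.01, 5),
                      se_exp = rep(0.002, 5))
  wm <- mr_weighted_median(insts, n_boot = 300, seed = 5)
  expect_equal(wm$beta, 0.3, tolerance = 1e-12)
  expect_lt(wm$se, 0.05)
})

test_that("the weighted median resists gross outliers when >50% of weight is valid", {
  withr::with_seed(6, {
    theta <- 0.4
    hits <- 0
    for (r in 1:20) {
      gamma <- runif(12, 0.2, 0.5)
      by <- rnorm(12, theta * gamma, 0.01)
      by[1:3] <- by[1:3] + 2  # gross pleiotropic outliers, <50% of weight
      insts <- make_insts(gamma, by, se_out = rep(0.01, 12))
      wm <- mr_weighted_median(insts, n_boot = 10, seed = r)
      if (abs(wm$beta - theta) < 0.05) hits <- hits + 1
    }
    expect_gte(hits, 19)
  })
})

test_that("odds-ratio conversion matches the closed form", {
  ci <- to_odds_ratio(0, 0.1)
  expect_equal(ci$or_, 1)
  expect_equal(ci$ci_low, exp(-1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(ci$ci_high, exp(1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(round(ci$ci_low, 3), 0.822)
  expect_equal(round(ci$ci_high, 3), 1.217)

  tiny <- to_odds_ratio(log(2), 1e-12)
  expect_equal(tiny$or_, 2)
  expect_equal(tiny$ci_low, 2, tolerance = 1e-9)
  expect_equal(tiny$ci_high, 2, tolerance = 1e-9)
  # a log-odds estimate of 0.916 corresponds to an OR of 2.50 with this transform
  expect_equal(round(to_odds_ratio(0.916, 0.33)$or_, 2), 2.5)
})

test_that("p-values are two-sided in (0, 1] and p(beta = 0) = 1", {
  null_insts <- make_insts(c(0.5, 0.4, 0.25), c(0, 0, 0), c(0.05, 0.08, 0.05))
  expect_equal(mr_ivw(null_insts, model = "fixed")$pval, 1)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      insts <- make_insts(runif(5, 0.1, 0.5), rnorm(5, 0.05, 0.1),
                          runif(5, 0.02, 0.1))
      for (p in c(mr_ivw(insts)$pval, mr_egger(insts)$pval,
                  mr_weighted_median(insts, n_boot = 20, seed = seed)$pval)) {
        expect_gt(p, 0); expect_lte(p, 1)
      }
    })
  }
})

test_that("mr_estimate returns one tidy row per runnable method and skips the rest", {
  insts <- fixture3()
  res <- mr_estimate(insts, n_boot = 50, seed = 1)
  expect_equal(res$method, c("ivw_re", "egger", "weighted_median"))
  expect_true(all(res$ci_low < res$or_ & res$or_ < res$ci_high))

  two <- insts[1:2, ]
  expect_message(res2 <- mr_estimate(two, n_boot = 50, seed = 1), "minimum 3")
  expect_equal(res2$method, "ivw_re")
  expect_match(attr(res2, "skipped")[["egger"]], "minimum 3")
})
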