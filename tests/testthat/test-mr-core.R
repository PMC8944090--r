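mk_stats <- function(df, trait = "t") {
  sumstats(dplyr::mutate(df, p = pmax(2 * pnorm(-abs(beta / se)),
                                      .Machine$double.xmin)),
           trait_id = trait)
}

test_that("harmonisation orients, flips and audits correctly", {
  exp <- mk_stats(tibble::tibble(
    snp = c("s1", "s2", "s3", "s4", "s5"), chr = 1L, pos = 1:5 * 1000L,
    ea = c("A", "A", "A", "A", "A"), oa = c("G", "G", "T", "T", "C"),
    eaf = c(0.3, 0.3, 0.50, 0.2, 0.3), beta = 0.1, se = 0.01, n = 1e4), "x")
  out <- mk_stats(tibble::tibble(
    snp = c("s1", "s2", "s3", "s4", "s5"), chr = 1L, pos = 1:5 * 1000L,
    ea = c("A", "G", "A", "T", "A"), oa = c("G", "A", "T", "A", "G"),
    eaf = c(0.3, 0.7, 0.50, 0.75, 0.3), beta = c(0.05, 0.05, 0.05, 0.05, 0.05),
    se = 0.01, n = 1e4), "y")
  h <- harmonise(exp, out)

  # s1 identical alleles: untouched
  expect_equal(h$beta_out[h$snp == "s1"], 0.05)
  expect_equal(h$action[h$snp == "s1"], "kept")
  # s2 swapped alleles: beta negated, eaf complemented
  expect_equal(h$beta_out[h$snp == "s2"], -0.05)
  expect_equal(h$eaf_out[h$snp == "s2"], 0.3)
  expect_equal(h$action[h$snp == "s2"], "flipped")
  # s3 A/T palindrome at eaf 0.5: dropped
  expect_false("s3" %in% h$snp)
  audit <- attr(h, "audit")
  expect_equal(audit$action[audit$snp == "s3"], "dropped_palindromic")
  # s4 A/T palindrome, informative eafs on opposite sides: flipped
  expect_equal(h$beta_out[h$snp == "s4"], -0.05)
  expect_equal(h$eaf_out[h$snp == "s4"], 0.25)
  # s5 allele pair not resolvable (A/C vs A/G): dropped with reason
  expect_equal(audit$action[audit$snp == "s5"], "dropped_mismatch")

  # idempotence: harmonising a harmonised set changes nothing
  expect_identical(harmonise(h, out), h)

  expect_error(harmonise(exp[0, ], out), "share no SNPs")
})

test_that("Wald ratios follow the delta method", {
  h <- fixed_harmonised_table()
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, h$beta_out / h$beta_exp)
  expect_equal(wr$se_ratio, h$se_out / abs(h$beta_exp))
  # (0.1, 0.05, 0.01) -> ratio 0.5, se 0.1
  h2 <- h
  h2$beta_exp[1] <- 0.1; h2$beta_out[1] <- 0.05; h2$se_out[1] <- 0.01
  expect_equal(wald_ratios(h2)$ratio[1], 0.5)
  expect_equal(wald_ratios(h2)$se_ratio[1], 0.1)
  # doubling both betas leaves the ratio unchanged
  h3 <- h
  h3$beta_exp <- 2 * h$beta_exp; h3$beta_out <- 2 * h$beta_out
  expect_equal(wald_ratios(h3)$ratio, wr$ratio)
  # zero exposure beta excluded with a warning
  h4 <- h
  h4$beta_exp[2] <- 0
  expect_warning(wr4 <- wald_ratios(h4), "zero exposure")
  expect_equal(nrow(wr4), nrow(h) - 1)
})

test_that("IVW matches its algebraic identities and the homogeneous limit", {
  h <- fixed_harmonised_table()
  res <- mr_ivw(h)
  # weighted-least-squares oracle (lm through the origin)
  oracle <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
  expect_equal(res$estimate, unname(coef(oracle)), tolerance = 1e-10)
  # identity with the inverse-variance weighted mean of Wald ratios
  wr <- wald_ratios(h)
  expect_equal(res$estimate, sum(wr$w * wr$ratio) / sum(wr$w),
               tolerance = 1e-10)
  # sign-flip invariance per SNP
  h2 <- h
  h2$beta_exp[2] <- -h$beta_exp[2]; h2$beta_out[2] <- -h$beta_out[2]
  expect_equal(mr_ivw(h2)$estimate, res$estimate, tolerance = 1e-12)

  # all ratios equal: estimate c, Q = 0, SE at the fixed-effect value
  hc <- h
  hc$beta_out <- 0.4 * hc$beta_exp
  resc <- mr_ivw(hc)
  expect_equal(resc$estimate, 0.4, tolerance = 1e-12)
  expect_equal(resc$Q, 0, tolerance = 1e-20)
  expect_equal(resc$se, 1 / sqrt(sum(hc$beta_exp^2 / hc$se_out^2)))

  expect_true(mr_ivw(subset_harmonised(h, c(TRUE, rep(FALSE, 4))))$skipped)
})

test_that("Cochran's Q matches direct summation and is order invariant", {
  h <- fixed_harmonised_table()
  est <- mr_ivw(h)$estimate
  q <- cochran_q(h)
  wr <- wald_ratios(h)
  expect_equal(q$Q, sum(wr$w * (wr$ratio - est)^2), tolerance = 1e-12)
  expect_equal(q$df, 4)
  expect_equal(q$p, pchisq(q$Q, 4, lower.tail = FALSE))
  perm <- subset_harmonised(h, rep(TRUE, 5))[c(3, 1, 5, 2, 4), ]
  perm <- structure(perm, exposure = "x", outcome = "y",
                    class = class(h))
  expect_equal(cochran_q(perm)$Q, q$Q, tolerance = 1e-12)
  hc <- h
  hc$beta_out <- 0.4 * hc$beta_exp
  expect_equal(cochran_q(hc)$Q, 0, tolerance = 1e-18)
  expect_false(cochran_q(hc)$heterogeneity)
})

test_that("MR-Egger separates slope from directional pleiotropy", {
  h <- fixed_harmonised_table()
  # points exactly on a line through the origin: intercept 0, slope = IVW
  hl <- h
  hl$beta_out <- 0.4 * hl$beta_exp
  eg <- mr_egger(hl)
  expect_equal(eg$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(eg$estimate, mr_ivw(hl)$estimate, tolerance = 1e-10)

  # weighted regression oracle with intercept (after positive orientation)
  flip <- sign(h$beta_exp)
  o <- lm(I(h$beta_out * flip) ~ I(h$beta_exp * flip),
          weights = 1 / h$se_out^2)
  ego <- mr_egger(h)
  expect_equal(ego$estimate, unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(ego$egger_intercept, unname(coef(o)[1]), tolerance = 1e-10)

  # equal exposure SEs: I2_GX equals the closed form 1 - (k-1)/Q_GX
  he <- h
  he$se_exp <- rep(0.01, 5)
  bx <- abs(he$beta_exp)
  q_gx <- sum((bx - mean(bx))^2 / 0.01^2)
  expect_equal(mr_egger(he)$i2_gx, 1 - 4 / q_gx, tolerance = 1e-12)

  expect_true(mr_egger(subset_harmonised(h, c(TRUE, TRUE, FALSE, FALSE,
                                              FALSE)))$skipped)

  # injected directional pleiotropy is recovered by the intercept; strong
  # instruments (large exposure n) keep the NOME dilution of the intercept
  # negligible -- the weak-instrument case is SIMEX's job
  ints <- sapply(1:40, function(s) {
    hp <- make_harmonised(k = 40, theta = 0.1, n_exp = 5e6, seed = 1000 + s,
                          pleiotropy = rnorm(40, 0.02, 0.002))
    mr_egger(hp)$egger_intercept
  })
  expect_lt(abs(mean(ints) - 0.02), 2 * sd(ints) / sqrt(length(ints)))
})

test_that("SIMEX extrapolation corrects Egger dilution", {
  # NOME satisfied (tiny exposure SEs): corrected ~ naive
  h <- make_harmonised(k = 30, theta = 0.1, n_exp = 5e6, seed = 1)
  sx <- simex_egger(h, n_boot = 200, seed = 2)
  expect_lt(abs(sx$estimate - sx$naive_estimate), 0.005)

  # determinism
  sx2 <- simex_egger(h, n_boot = 200, seed = 2)
  expect_identical(sx$estimate, sx2$estimate)

  # dilution scenario: weak exposure precision attenuates naive Egger;
  # SIMEX moves the slope back toward the truth in most replicates
  # (100 replicates, n_boot scaled to 200 to keep the suite fast)
  theta <- 0.3
  wins <- sapply(1:100, function(s) {
    hd <- make_harmonised(k = 30, theta = theta, n_exp = 1200, n_out = 50000,
                          r2_target = 0.05, seed = 2000 + s)
    naive <- mr_egger(hd)
    corr <- simex_egger(hd, n_boot = 200, seed = s)
    abs(corr$estimate - theta) < abs(naive$estimate - theta)
  })
  expect_gte(mean(wins), 0.60)
  expect_error(simex_egger(h, lambdas = c(0, 1)), "3 distinct")
})

test_that("weighted median behaves like a robust midpoint", {
  h <- fixed_harmonised_table()
  # equal weights, odd k: the middle ratio
  he <- h
  he$se_out <- 0.01
  he$beta_out <- he$beta_exp * c(0.1, 0.2, 0.3, 0.4, 0.5)
  he$se_out <- he$se_out * abs(he$beta_exp) * 10  # equal ratio weights
  wm <- weighted_median(he, n_boot = 100, seed = 1)
  expect_equal(wm$estimate, 0.3, tolerance = 1e-10)

  # a wild outlier carrying little weight barely moves the estimate
  hb <- make_harmonised(k = 31, theta = 0.1, n_exp = 1e5, n_out = 1e5,
                        r2_target = 0.05, seed = 3)
  wm0 <- weighted_median(hb, n_boot = 300, seed = 4)
  wr <- wald_ratios(hb)
  i_min <- which.min(wr$w)
  expect_lt(wr$w[i_min] / sum(wr$w), 0.1)
  hb_out <- hb
  hb_out$beta_out[i_min] <- hb_out$beta_out[i_min] + 1  # one wild ratio
  wm1 <- weighted_median(hb_out, n_boot = 300, seed = 4)
  expect_lt(abs(wm1$estimate - wm0$estimate), wm0$se)

  # bootstrap SE tracks the replicate SD within 30% (200 replicates)
  reps <- sapply(1:200, function(s) {
    weighted_median(make_harmonised(k = 25, theta = 0.1, seed = 3000 + s),
                    n_boot = 2, seed = 1)$estimate
  })
  se_boot <- weighted_median(make_harmonised(k = 25, theta = 0.1, seed = 3001),
                             n_boot = 500, seed = 5)$se
  expect_equal(se_boot, sd(reps), tolerance = 0.3)
})

test_that("weighted mode finds the plurality cluster", {
  h <- fixed_harmonised_table()
  hc <- h
  hc$beta_out <- 0.25 * hc$beta_exp
  expect_equal(weighted_mode(hc, n_boot = 50, seed = 1)$estimate, 0.25,
               tolerance = 1e-8)

  # two clusters: 60% of weight at ratio 0.1, 40% at 0.5
  k <- 10
  df <- tibble::tibble(
    snp = paste0("s", 1:k), ea = "A", oa = "G",
    beta_exp = rep(0.1, k), se_exp = 0.005, eaf_exp = 0.4,
    beta_out = 0.1 * c(rep(0.1, 6), rep(0.5, 4)), se_out = 0.004,
    eaf_out = 0.4, action = "kept")
  hm <- structure(df, exposure = "x", outcome = "y",
                  outcome_type = "continuous", audit = df[0, ], k = k,
                  class = c("harmonised_set", class(df)))
  expect_equal(weighted_mode(hm, n_boot = 50, seed = 2)$estimate, 0.1,
               tolerance = 0.02)

  # seeded bootstrap SE is reproducible
  m1 <- weighted_mode(hm, n_boot = 100, seed = 3)
  m2 <- weighted_mode(hm, n_boot = 100, seed = 3)
  expect_identical(m1$se, m2$se)
})

test_that("mean F statistic reproduces the printed worked example", {
  row <- dplyr::filter(ukb_instrument_strength(), trait == "menarche")
  f <- mean_f_statistic(row$r2, row$n, row$nsnp)
  # the printed r2 has two significant digits; the achievable window for F
  # is set by r2 +/- half an ulp of the printed value
  f_lo <- mean_f_statistic(row$r2 - 5e-4, row$n, row$nsnp)
  f_hi <- mean_f_statistic(row$r2 + 5e-4, row$n, row$nsnp)
  expect_gte(row$f_printed, f_lo)
  expect_lte(row$f_printed, f_hi)
  expect_equal(f, row$f_printed, tolerance = 0.01)  # relative 1%

  expect_equal(mean_f_statistic(0, 1000, 10), 0)
  expect_error(mean_f_statistic(1, 1000, 10), "r2")
  expect_error(mean_f_statistic(0.1, 10, 10), "exceed")
})
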