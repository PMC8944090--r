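test_that("genotype simulation respects Hardy-Weinberg and determinism", {
  panel <- simulate_genotypes(50000, genotype_blocks(1, 1, rho = 0, maf = 0.5),
                              seed = 1)
  # E[dosage] = 2 * maf = 1; MC tolerance ~4 SDs of the mean
  expect_equal(mean(panel$dosages), 1, tolerance = 0.02)
  expect_true(all(panel$dosages %in% 0:2))

  p1 <- simulate_genotypes(500, genotype_blocks(3, 5, rho = 0.4), seed = 7)
  p2 <- simulate_genotypes(500, genotype_blocks(3, 5, rho = 0.4), seed = 7)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$snp_meta, p2$snp_meta)

  expect_error(simulate_genotypes(1, genotype_blocks(1, 1)), "integer >= 2")
  expect_error(simulate_genotypes(10, genotype_blocks(1, 2, rho = 1)),
               "rho")
})

test_that("within-block dosage r2 matches a brute-force latent-threshold oracle", {
  # oracle: simulate the same latent AR thresholding model at n = 1e6 with
  # plain base R, no package code
  oracle_r2 <- local({
    set.seed(99)
    n <- 1e6; rho <- 0.8; maf <- 0.3; thr <- qnorm(maf)
    hap <- function() {
      z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      cbind(z1 < thr, z2 < thr)
    }
    d <- hap() + hap()
    cor(d[, 1], d[, 2])^2
  })
  panel <- simulate_genotypes(
    100000, genotype_blocks(1, 2, rho = 0.8, maf = 0.3), seed = 5)
  emp_r2 <- cor(panel$dosages[, 1], panel$dosages[, 2])^2
  expect_equal(emp_r2, oracle_r2, tolerance = 0.02)
})

test_that("trait simulation honours the causal configuration", {
  reg2 <- tibble::tibble(trait = c("x", "y"), type = "continuous")
  panel <- simulate_genotypes(50000, genotype_blocks(8, 10, rho = 0),
                              seed = 2)

  # pure noise: unit variance, near-zero cross-correlation
  cfg0 <- causal_config(traits = reg2, n_snps_per_trait = 10,
                        h2 = c(x = 0, y = 0),
                        theta = tibble::tibble(from = character(),
                                               to = character(),
                                               theta = numeric()),
                        confounder_gamma = c(x = 0, y = 0),
                        prevalence = numeric(0), seed = 3)
  tr0 <- simulate_traits(panel, cfg0)
  expect_equal(var(tr0$x), 1, tolerance = 0.02)
  expect_equal(var(tr0$y), 1, tolerance = 0.02)
  expect_lt(abs(cor(tr0$x, tr0$y)), 0.02)

  # single edge theta = 0.5: OLS slope of target on source ~ 0.5
  cfg1 <- causal_config(traits = reg2, n_snps_per_trait = 10,
                        h2 = c(x = 0.2, y = 0.1),
                        theta = tibble::tibble(from = "x", to = "y",
                                               theta = 0.5),
                        confounder_gamma = c(x = 0, y = 0),
                        prevalence = numeric(0), seed = 4)
  tr1 <- simulate_traits(panel, cfg1)
  slope <- coef(lm(tr1$y ~ tr1$x))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.02)

  # variance accounting: regression of trait on its causal dosages gives h2
  truth <- true_effects(tr1, "direct")
  snps_x <- truth$snp[truth$trait == "x"]
  r2 <- summary(lm(tr1$x ~ panel$dosages[, snps_x]))$r.squared
  expect_equal(r2, 0.2, tolerance = 0.02)

  # binary liability threshold hits the configured prevalence
  pan8 <- simulate_genotypes(50000, genotype_blocks(48, 10, rho = 0), seed = 5)
  tr8 <- simulate_traits(pan8, causal_config(seed = 6))
  expect_equal(mean(tr8$parous), 0.8131, tolerance = 0.01)

  # identical config + seed => bit-identical traits
  tr8b <- simulate_traits(pan8, causal_config(seed = 6))
  expect_identical(as.data.frame(tr8), as.data.frame(tr8b))
})

test_that("invalid causal configurations are rejected", {
  reg2 <- tibble::tibble(trait = c("x", "y"), type = "continuous")
  cyc <- tibble::tibble(from = c("x", "y"), to = c("y", "x"), theta = 0.1)
  expect_error(causal_config(traits = reg2, theta = cyc,
                             h2 = c(x = 0.1, y = 0.1),
                             confounder_gamma = c(x = 0, y = 0),
                             prevalence = numeric(0)),
               "cycle")
  expect_error(causal_config(traits = reg2, h2 = c(x = 1.2, y = 0),
                             theta = tibble::tibble(from = character(),
                                                    to = character(),
                                                    theta = numeric()),
                             confounder_gamma = c(x = 0, y = 0),
                             prevalence = numeric(0)),
               "h2")
  expect_error(causal_config(traits = reg2, h2 = c(x = 0.5, y = 0.5),
                             theta = tibble::tibble(from = "x", to = "y",
                                                    theta = 0.9),
                             confounder_gamma = c(x = 0, y = 0),
                             prevalence = numeric(0)),
               "variance budget")
  expect_error(
    causal_config(traits = tibble::tibble(trait = "b", type = "binary"),
                  h2 = c(b = 0.1),
                  theta = tibble::tibble(from = character(),
                                         to = character(), theta = numeric()),
                  confounder_gamma = c(b = 0),
                  prevalence = numeric(0)),
    "prevalence")
})

test_that("analytic summary statistics are calibrated and self-consistent", {
  reg1 <- tibble::tibble(trait = "x", type = "continuous")
  panel <- simulate_genotypes(2000, genotype_blocks(100, 10, rho = 0),
                              seed = 10)
  cfg <- causal_config(traits = reg1, n_snps_per_trait = 0, h2 = c(x = 0),
                       theta = tibble::tibble(from = character(),
                                              to = character(),
                                              theta = numeric()),
                       confounder_gamma = c(x = 0), prevalence = numeric(0),
                       seed = 11)
  tr <- simulate_traits(panel, cfg)

  # null calibration: p-values uniform across many SNPs and draws
  ps <- unlist(lapply(1:2, function(s) {
    emit_sumstats(panel, tr, "x", "analytic", n_eff = 10000, seed = s)$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # emitted p equals the two-sided normal tail of beta/se
  ss <- emit_sumstats(panel, tr, "x", "analytic", n_eff = 10000, seed = 3)
  expect_equal(ss$p, 2 * pnorm(-abs(ss$beta / ss$se)), tolerance = 1e-12)

  # determinism
  expect_identical(as.data.frame(ss),
                   as.data.frame(emit_sumstats(panel, tr, "x", "analytic",
                                               n_eff = 10000, seed = 3)))
  expect_error(emit_sumstats(panel, tr, "nope", "analytic"), "unknown trait")
  expect_error(emit_sumstats(panel, tr, "x", "analytic", n_eff = 5), "n_eff")
})

test_that("analytic SEs match the replicate SD of individual-mode betas", {
  # 300 GWAS replicates on a small panel (replicate-count scaled down from
  # 500 to keep the suite fast; the 5% check is on the SD ratio)
  reg1 <- tibble::tibble(trait = "x", type = "continuous")
  panel <- simulate_genotypes(2000, genotype_blocks(3, 10, rho = 0), seed = 20)
  # null trait so the per-SNP truth (zero) is identical across replicates and
  # the replicate SD isolates pure sampling noise
  cfg <- causal_config(traits = reg1, n_snps_per_trait = 0, h2 = c(x = 0),
                       theta = tibble::tibble(from = character(),
                                              to = character(),
                                              theta = numeric()),
                       confounder_gamma = c(x = 0), prevalence = numeric(0),
                       seed = 21)
  betas <- sapply(1:300, function(s) {
    cfg$seed <- s
    tr <- simulate_traits(panel, cfg)
    run_gwas(panel, tr, "x")$beta
  })
  emp_sd <- apply(betas, 1, sd)
  tr <- simulate_traits(panel, cfg)
  analytic_se <- emit_sumstats(panel, tr, "x", "analytic",
                               n_eff = 2000, seed = 1)$se
  ratio <- mean(emp_sd / analytic_se)
  expect_equal(ratio, 1, tolerance = 0.05)
})
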