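test_that("rank-based inverse normal transformation matches Blom scores", {
  expect_equal(rank_inverse_normal(c(1, 2, 3))[2], 0)
  v <- c(5, 1, 9, 3, 7)
  expect_equal(rank_inverse_normal(v),
               qnorm((rank(v) - 0.375) / 5.25))
  x <- sort(runif(50))
  expect_true(all(diff(rank_inverse_normal(x)) > 0))
  withna <- c(1, NA, 2, 3)
  out <- rank_inverse_normal(withna)
  expect_true(is.na(out[2]) && !anyNA(out[-2]))
  expect_error(rank_inverse_normal(c(NA, NA, 1)), "non-missing")
  # ties share the average-rank score
  expect_equal(rank_inverse_normal(c(1, 1, 2))[1],
               rank_inverse_normal(c(1, 1, 2))[2])
})

test_that("per-SNP association scan estimates what it should", {
  set.seed(101)
  panel <- simulate_genotypes(3000, genotype_blocks(4, 5, rho = 0), seed = 1)
  n <- 3000
  base <- tibble::tibble(id = 1:n, age = rnorm(n), batch = rbinom(n, 1, 0.5))

  # perfect signal: trait exactly 2 x dosage of SNP 1
  tt <- base
  tt$y <- 2 * panel$dosages[, 1]
  attr(tt, "types") <- c(y = "continuous")
  g <- run_gwas(panel, tt, "y")
  expect_equal(g$beta[1], 2, tolerance = 1e-8)
  expect_lt(g$p[1], 1e-100)

  # covariate identical to the trait absorbs everything
  tt2 <- base
  tt2$y <- rnorm(n) + 0.3 * panel$dosages[, 2]
  tt2$age <- tt2$y
  attr(tt2, "types") <- c(y = "continuous")
  g2 <- run_gwas(panel, tt2, "y")
  expect_lt(max(abs(g2$beta)), 1e-8)

  # null SNPs give uniform p-values (KS over 2000 SNPs)
  pan_null <- simulate_genotypes(400, genotype_blocks(200, 10, rho = 0),
                                 seed = 2)
  tt3 <- tibble::tibble(id = 1:400, age = rnorm(400),
                        batch = rbinom(400, 1, 0.5), y = rnorm(400))
  attr(tt3, "types") <- c(y = "continuous")
  g3 <- run_gwas(pan_null, tt3, "y")
  expect_gt(stats::ks.test(g3$p, "punif")$p.value, 0.01)

  # monomorphic SNP is excluded with a message
  pan_mono <- pan_null
  pan_mono$dosages[, 3] <- 0L
  expect_message(g4 <- run_gwas(pan_mono, tt3, "y"), "monomorphic")
  expect_equal(nrow(g4), nrow(g3) - 1)

  # binary traits: logistic log-odds with the right sign and scale
  tt5 <- base
  eta <- -1 + 0.5 * panel$dosages[, 1]
  tt5$d <- rbinom(n, 1, plogis(eta))
  attr(tt5, "types") <- c(d = "binary")
  g5 <- run_gwas(panel, tt5, "d")
  expect_equal(g5$beta[1], 0.5, tolerance = 0.2)
})

test_that("standardisation of summary statistics is exact and idempotent", {
  p <- make_pair_sumstats(k = 30, seed = 3)
  s <- p$exposure

  expect_equal(as.data.frame(standardise_sumstats(s, trait_sd = 1))[
    , c("beta", "se")], as.data.frame(s)[, c("beta", "se")])

  # scaling the trait by 3 scales betas by 3; standardising recovers them
  s3 <- s
  s3$beta <- s$beta * 3
  s3$se <- s$se * 3
  back <- standardise_sumstats(s3, trait_sd = 3)
  expect_equal(back$beta, s$beta, tolerance = 1e-10)
  expect_equal(back$se, s$se, tolerance = 1e-10)

  # summary-only route agrees with the known-SD route within 1%
  sum_route <- standardise_sumstats(s)
  sd_route <- standardise_sumstats(s, trait_sd = 1)  # traits are unit SD
  expect_equal(sum_route$beta, sd_route$beta, tolerance = 0.01)
  expect_equal(sum_route$se, sd_route$se, tolerance = 0.01)

  expect_warning(standardise_sumstats(sum_route), "already")
})

test_that("instrument selection clumps greedily and deterministically", {
  set.seed(103)
  # panel: two tight blocks plus independent SNPs
  panel <- simulate_genotypes(
    5000, genotype_blocks(4, 2, rho = c(0.95, 0, 0, 0)), seed = 4)
  meta <- panel$snp_meta
  mk_stats <- function(p_values) {
    z <- qnorm(p_values / 2, lower.tail = FALSE)
    eaf <- pmin(pmax(colMeans(panel$dosages) / 2, 0.01), 0.99)
    se <- 1 / sqrt(2 * eaf * (1 - eaf) * 50000)
    sumstats(tibble::tibble(
      snp = meta$snp, chr = meta$chr, pos = meta$pos, ea = meta$ea,
      oa = meta$oa, eaf = eaf, beta = z * se, se = se, p = p_values,
      n = 50000), trait_id = "x")
  }
  pvals <- c(1e-20, 1e-10,   # block 1: r2 ~ 0.9, 10 kb apart
             1e-12, 0.5, 6e-8, 0.9, 1e-9, 0.2)
  st <- mk_stats(pvals)

  sel <- select_instruments(st, panel, clump_r2 = 0.1, clump_kb = 10000)
  # the weaker SNP of the LD pair is clumped away; p = 6e-8 fails p < 5e-8
  expect_true(meta$snp[1] %in% sel$snp)
  expect_false(meta$snp[2] %in% sel$snp)
  expect_false(meta$snp[5] %in% sel$snp)
  expect_setequal(sel$snp, meta$snp[c(1, 3, 7)])

  # row-order invariance
  shuf <- st[sample.int(nrow(st)), ]
  sel2 <- select_instruments(shuf, panel, clump_r2 = 0.1, clump_kb = 10000)
  expect_identical(as.data.frame(sel), as.data.frame(sel2))

  # clump_r2 = 1 keeps every survivor; clump_kb = 0 only hits co-located SNPs
  sel3 <- select_instruments(st, panel, clump_r2 = 1, clump_kb = 10000)
  expect_equal(nrow(sel3), sum(pvals < 5e-8))
  sel4 <- select_instruments(st, panel, clump_r2 = 0.1, clump_kb = 0)
  expect_equal(nrow(sel4), sum(pvals < 5e-8))

  # nothing survives => explicit empty status
  empty <- select_instruments(mk_stats(rep(0.5, 8)), panel)
  expect_equal(nrow(empty), 0)
  expect_identical(attr(empty, "status"), "empty")
})

test_that("instrument r2_total matches variance explained by joint OLS", {
  reg1 <- tibble::tibble(trait = "x", type = "continuous")
  panel <- simulate_genotypes(20000, genotype_blocks(20, 1, rho = 0), seed = 6)
  cfg <- causal_config(traits = reg1, n_snps_per_trait = 15, h2 = c(x = 0.1),
                       theta = tibble::tibble(from = character(),
                                              to = character(),
                                              theta = numeric()),
                       confounder_gamma = c(x = 0), prevalence = numeric(0),
                       seed = 7)
  tr <- simulate_traits(panel, cfg)
  st <- standardise_sumstats(run_gwas(panel, tr, "x"))
  sel <- select_instruments(st, panel, p_threshold = 1e-4)
  joint <- summary(lm(tr$x ~ panel$dosages[, sel$snp]))$r.squared
  expect_equal(attr(sel, "r2_total"), joint, tolerance = 0.05)
})

test_that("cohort splitting partitions deterministically", {
  set.seed(102)
  panel <- simulate_genotypes(100, genotype_blocks(2, 5, rho = 0), seed = 8)
  tt <- tibble::tibble(id = 1:100, age = rnorm(100),
                       batch = rbinom(100, 1, 0.5), y = rnorm(100))
  attr(tt, "types") <- c(y = "continuous")
  sp <- split_cohort(panel, tt, seed = 9)
  expect_equal(length(sp$a$idx), 50)
  expect_equal(length(sp$b$idx), 50)
  expect_length(intersect(sp$a$idx, sp$b$idx), 0)
  expect_setequal(union(sp$a$idx, sp$b$idx), 1:100)
  sp2 <- split_cohort(panel, tt, seed = 9)
  expect_identical(sp$a$idx, sp2$a$idx)
  expect_error(split_cohort(subset_panel(panel, 1:3), tt[1:3, ], 1),
               "at least 4")
})
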