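# Shared fixtures, built in code. Sample sizes here are deliberately modest
# so the default suite stays fast; the statistical scale of each check is
# set inside the test that needs it.

# Analytic two-sample sumstats pair for estimator tests: k unlinked SNPs,
# exposure effects sized to a target aggregate r2, outcome = theta * exposure
# (+ optional per-SNP pleiotropy added to the outcome betas), independent
# Gaussian sampling noise on both sides.
make_pair_sumstats <- function(k = 50, theta = 0.1, n_exp = 20000,
                               n_out = 20000, r2_target = 0.03,
                               pleiotropy = rep(0, k), seed = 1,
                               effect_dist = c("normal", "equal")) {
  effect_dist <- match.arg(effect_dist)
  set.seed(seed)
  eaf <- runif(k, 0.1, 0.9)
  # standardized per-SNP effects with aggregate variance explained r2_target
  b_std <- if (effect_dist == "normal") rnorm(k) else sample(c(-1, 1), k, TRUE)
  b_std <- b_std * sqrt(r2_target / sum(b_std^2))
  beta_true <- b_std / sqrt(2 * eaf * (1 - eaf))
  se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
  se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out)
  bases <- cbind(ea = rep(c("A", "C"), length.out = k),
                 oa = rep(c("G", "T"), length.out = k))  # non-palindromic
  mk <- function(beta_hat, se, n, trait) {
    mrfactors::sumstats(
      tibble::tibble(snp = sprintf("rs%04d", seq_len(k)), chr = 1L,
                     pos = seq_len(k) * 10000L, ea = bases[, "ea"],
                     oa = bases[, "oa"], eaf = eaf, beta = beta_hat, se = se,
                     p = pmax(2 * stats::pnorm(-abs(beta_hat / se)),
                              .Machine$double.xmin),
                     n = n),
      trait_id = trait)
  }
  # directional pleiotropy is injected relative to the effect-increasing
  # allele (sign of the true exposure effect), the orientation Egger fits in
  exposure <- mk(rnorm(k, beta_true, se_exp), se_exp, n_exp, "x")
  outcome <- mk(rnorm(k, theta * beta_true + pleiotropy * sign(beta_true),
                      se_out), se_out, n_out, "y")
  list(exposure = exposure, outcome = outcome, beta_true = beta_true,
       eaf = eaf, se_exp = se_exp, se_out = se_out)
}

make_harmonised <- function(...) {
  p <- make_pair_sumstats(...)
  mrfactors::harmonise(p$exposure, p$outcome)
}

# a small fixed harmonised table used by the exact-arithmetic oracle tests
fixed_harmonised_table <- function() {
  df <- tibble::tibble(
    snp = paste0("s", 1:5), ea = "A", oa = "G",
    beta_exp = c(0.10, 0.08, -0.12, 0.15, 0.09),
    se_exp   = c(0.010, 0.012, 0.011, 0.015, 0.009),
    eaf_exp  = c(0.3, 0.4, 0.5, 0.2, 0.6),
    beta_out = c(0.052, 0.038, -0.070, 0.071, 0.049),
    se_out   = c(0.011, 0.013, 0.012, 0.016, 0.010),
    eaf_out  = c(0.3, 0.4, 0.5, 0.2, 0.6),
    action = "kept")
  structure(df, exposure = "x", outcome = "y", outcome_type = "continuous",
            audit = df[0, ], k = nrow(df),
            class = c("harmonised_set", class(df)))
}

# tiny LD-score table on independent synthetic SNPs, for regression tests
# that draw z-scores straight from the LDSC generative model
model_ld_table <- function(m = 2000, seed = 1, l2_range = c(1, 4)) {
  set.seed(seed)
  structure(
    tibble::tibble(snp = paste0("s", seq_len(m)), chr = 1L,
                   pos = seq_len(m) * 10000L, ea = "A", oa = "C",
                   l2 = runif(m, l2_range[1], l2_range[2])),
    n_ref = 20000L,
    class = c("ldscore_table", "tbl_df", "tbl", "data.frame"))
}
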