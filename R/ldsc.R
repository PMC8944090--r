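#' Compute LD scores from a reference panel
#'
#' The LD score of SNP j is the sum over SNPs k within `window_kb` (same
#' chromosome, including j itself) of the adjusted squared correlation
#' `r2_adj = r2 - (1 - r2) / (n_ref - 2)`, which removes the finite-sample
#' upward bias of the sample r-squared (the self term contributes exactly 1).
#'
#' @param panel A `genotype_panel` with at least 50 individuals.
#' @param window_kb Window half-width in kb (> 0).
#' @return An `ldscore_table` tibble (`snp, chr, pos, ea, oa, l2`) with
#'   attribute `n_ref`.
#' @export
compute_ld_scores <- function(panel, window_kb = 1000) {
  if (window_kb <= 0) abort("window_kb must be > 0")
  n_ref <- nrow(panel$dosages)
  if (n_ref < 50) abort("need at least 50 reference individuals")
  meta <- panel$snp_meta
  l2 <- numeric(nrow(meta))
  for (cc in unique(meta$chr)) {
    idx <- which(meta$chr == cc)
    R2 <- cor(panel$dosages[, idx, drop = FALSE])^2
    adj <- R2 - (1 - R2) / (n_ref - 2)
    dist <- abs(outer(meta$pos[idx], meta$pos[idx], "-"))
    adj[dist > window_kb * 1000] <- 0
    l2[idx] <- rowSums(adj)
  }
  out <- tibble(snp = meta$snp, chr = meta$chr, pos = meta$pos,
                ea = meta$ea, oa = meta$oa, l2 = l2)
  structure(out, n_ref = n_ref, class = c("ldscore_table", class(out)))
}

#' Munge summary statistics for LD score regression
#'
#' Intersects with the reference SNP list, drops strand-ambiguous (A/T, G/C)
#' SNPs, aligns the z-score sign to the reference effect allele (resolving
#' strand flips by complement), and removes SNPs inside exclusion regions
#' (default the extended MHC, chr6:26-34 Mb, 1-based inclusive).
#'
#' @param stats A [sumstats()] tibble.
#' @param reference An `ldscore_table` (provides the reference SNP list and
#'   allele orientation); a real reference list can be substituted by any
#'   tibble with columns `snp, ea, oa`.
#' @param exclusion_regions Tibble `chr, start, end`; `NULL` for none.
#' @return A tibble `snp, z, n` aligned to the reference alleles.
#' @export
munge <- function(stats, reference,
                  exclusion_regions = tibble(chr = 6L, start = 26e6, end = 34e6)) {
  x <- as_tibble(stats)
  if (!is.null(exclusion_regions) && nrow(exclusion_regions)) {
    for (i in seq_len(nrow(exclusion_regions))) {
      drop <- x$chr == exclusion_regions$chr[i] &
        x$pos >= exclusion_regions$start[i] &
        x$pos <= exclusion_regions$end[i]
      x <- x[!drop, ]
    }
  }
  x <- x[!is_palindromic(x$ea, x$oa), ]
  ref <- as_tibble(reference)[, c("snp", "ea", "oa")]
  names(ref) <- c("snp", "ref_ea", "ref_oa")
  x <- inner_join(x, ref, by = "snp")
  if (nrow(x) == 0) abort("no SNPs shared with the reference list")
  same <- x$ea == x$ref_ea & x$oa == x$ref_oa
  swap <- x$ea == x$ref_oa & x$oa == x$ref_ea
  flip_same <- allele_complement(x$ea) == x$ref_ea &
    allele_complement(x$oa) == x$ref_oa
  flip_swap <- allele_complement(x$ea) == x$ref_oa &
    allele_complement(x$oa) == x$ref_ea
  sign <- rep(NA_real_, nrow(x))
  sign[same | flip_same] <- 1
  sign[swap | flip_swap] <- -1
  keep <- !is.na(sign)
  x <- x[keep, ]
  tibble(snp = x$snp, z = sign[keep] * x$beta / x$se, n = x$n)
}

# weighted simple regression y ~ 1 + x, full fit only
wls_fit <- function(x, y, w) {
  s <- c(sum(w), sum(w * x), sum(w * x^2), sum(w * y), sum(w * x * y))
  A <- matrix(c(s[1], s[2], s[2], s[3]), 2)
  solve(A, c(s[4], s[5]))
}

# weighted simple regression y ~ 1 + x with delete-a-block refits;
# returns full coefficients and a B x 2 matrix of leave-block-out coefficients
wls_jackknife <- function(x, y, w, block_id) {
  s <- cbind(w, w * x, w * x^2, w * y, w * x * y)
  tot <- colSums(s)
  solve_coef <- function(v) {
    A <- matrix(c(v[1], v[2], v[2], v[3]), 2)
    b <- c(v[4], v[5])
    solve(A, b)  # (intercept, slope)
  }
  full <- solve_coef(tot)
  bs <- rowsum(s, block_id)
  loo <- t(apply(bs, 1, function(b) solve_coef(tot - b)))
  list(full = full, loo = loo)
}

jackknife_se <- function(est_loo) {
  B <- length(est_loo)
  sqrt((B - 1) / B * sum((est_loo - mean(est_loo))^2))
}

make_blocks <- function(n_snps, n_blocks = 200, min_per_block = 10) {
  B <- max(2L, min(n_blocks, n_snps %/% min_per_block))
  sort(rep_len(seq_len(B), n_snps))
}

ldsc_merge <- function(ztab, ld) {
  m <- inner_join(as_tibble(ztab), as_tibble(ld)[, c("snp", "chr", "pos", "l2")],
                  by = "snp")
  arrange(m, .data$chr, .data$pos)
}

#' LD score regression for SNP heritability
#'
#' Regresses per-SNP chi-squared statistics on LD scores:
#' `E[chi2_j] = intercept + N * h2 * l_j / M`. Fitting is two-pass: an
#' unweighted fit initialises `h2`, then a weighted fit uses the
#' heteroskedasticity weights `1 / (2 * (intercept + N*h2*l/M)^2) * 1/l`.
#' Standard errors come from a delete-a-block jackknife over
#' position-contiguous blocks.
#'
#' @param ztab Munged z table (`snp, z, n`) from [munge()].
#' @param ld An `ldscore_table`.
#' @param N GWAS sample size (default median of `ztab$n`).
#' @param M Number of regression SNPs for the slope scaling (default the
#'   number of merged SNPs).
#' @param n_blocks Jackknife blocks (default 200, at least 10 SNPs each).
#' @param chisq_cap Optional winsorisation cap for chi-squared (e.g.
#'   `max(80, 0.001 * N)`); `NULL` (default) disables it.
#' @return List with `h2, h2_se, intercept, intercept_se, M, n_blocks,
#'   n_snps`.
#' @export
ldsc_h2 <- function(ztab, ld, N = NULL, M = NULL, n_blocks = 200,
                    chisq_cap = NULL) {
  m <- ldsc_merge(ztab, ld)
  if (nrow(m) < 200) abort("need at least 200 SNPs for LDSC")
  if (sd(m$l2) < 1e-12) abort("LD scores are degenerate (all equal)")
  N <- N %||% median(m$n)
  M <- M %||% nrow(m)
  chi2 <- m$z^2
  if (!is.null(chisq_cap)) chi2 <- pmin(chi2, chisq_cap)
  x <- m$l2 * N / M

  pass1 <- wls_fit(x, chi2, rep(1, nrow(m)))
  h2_init <- min(max(pass1[2], 0), 1)
  a_init <- max(pass1[1], 0.1)
  mu <- a_init + h2_init * x
  w <- 1 / (2 * mu^2) / pmax(m$l2, 1)

  blocks <- make_blocks(nrow(m), n_blocks)
  fit <- wls_jackknife(x, chi2, w, blocks)
  list(h2 = fit$full[2], h2_se = jackknife_se(fit$loo[, 2]),
       intercept = fit$full[1], intercept_se = jackknife_se(fit$loo[, 1]),
       M = M, n_blocks = max(blocks), n_snps = nrow(m))
}

#' Cross-trait LD score regression for genetic correlation
#'
#' Regresses `z1 * z2` on LD scores: `E[z1 z2] = intercept +
#' sqrt(N1*N2) * rho_g * l / M`. The free intercept absorbs sample overlap
#' (`n_overlap * pheno_corr / sqrt(N1 N2)` in expectation). The genetic
#' correlation is `rg = rho_g / sqrt(h2_1 * h2_2)` with the heritabilities
#' estimated by [ldsc_h2()] on the same merged SNP set. All standard errors
#' are delete-a-block jackknives over the same blocks, so the computation is
#' exactly symmetric in the two traits.
#'
#' @param z1,z2 Munged z tables sharing at least 200 SNPs.
#' @param ld An `ldscore_table`.
#' @param N1,N2 Sample sizes (defaults: medians of the `n` columns).
#' @param n_blocks Jackknife blocks.
#' @return A `ldsc_rg_result` list: `rg, rg_se, rg_p, rho_g, h2` (per-trait
#'   estimate and SE), `intercepts` (univariate and bivariate with SE),
#'   `M, n_blocks, n_snps, defined` (FALSE when either h2 estimate is <= 0,
#'   in which case `rg` is `NA`).
#' @export
ldsc_rg <- function(z1, z2, ld, N1 = NULL, N2 = NULL, n_blocks = 200) {
  ld_df <- as_tibble(ld)[, c("snp", "chr", "pos", "l2")]
  m <- inner_join(as_tibble(z1), as_tibble(z2), by = "snp",
                  suffix = c("_1", "_2")) |>
    inner_join(ld_df, by = "snp") |>
    arrange(.data$chr, .data$pos)
  if (nrow(m) < 200) abort("traits share fewer than 200 SNPs")
  if (sd(m$l2) < 1e-12) abort("LD scores are degenerate (all equal)")
  N1 <- N1 %||% median(m$n_1)
  N2 <- N2 %||% median(m$n_2)
  M <- nrow(m)
  blocks <- make_blocks(M, n_blocks)

  fit_h2 <- function(z, N) {
    x <- m$l2 * N / M
    chi2 <- z^2
    pass1 <- wls_fit(x, chi2, rep(1, M))
    h2_init <- min(max(pass1[2], 0), 1)
    mu <- max(pass1[1], 0.1) + h2_init * x
    w <- 1 / (2 * mu^2) / pmax(m$l2, 1)
    wls_jackknife(x, chi2, w, blocks)
  }
  f1 <- fit_h2(m$z_1, N1)
  f2 <- fit_h2(m$z_2, N2)

  xg <- m$l2 * sqrt(N1 * N2) / M
  y <- m$z_1 * m$z_2
  pass1 <- wls_fit(xg, y, 1 / pmax(m$l2, 1))
  mu1 <- max(f1$full[1], 0.1) + max(f1$full[2], 0) * m$l2 * N1 / M
  mu2 <- max(f2$full[1], 0.1) + max(f2$full[2], 0) * m$l2 * N2 / M
  mux <- pass1[1] + pass1[2] * xg
  w <- 1 / (mu1 * mu2 + mux^2) / pmax(m$l2, 1)
  fx <- wls_jackknife(xg, y, w, blocks)

  rho_g <- fx$full[2]
  h2_1 <- f1$full[2]
  h2_2 <- f2$full[2]
  defined <- h2_1 > 0 && h2_2 > 0
  rg <- if (defined) rho_g / sqrt(h2_1 * h2_2) else NA_real_
  rg_loo <- rep(NA_real_, max(blocks))
  if (defined) {
    ok <- f1$loo[, 2] > 0 & f2$loo[, 2] > 0
    rg_loo <- ifelse(ok, fx$loo[, 2] / sqrt(pmax(f1$loo[, 2], 1e-12) *
                                              pmax(f2$loo[, 2], 1e-12)), NA)
  }
  rg_se <- if (defined && all(is.finite(rg_loo))) jackknife_se(rg_loo) else NA_real_
  structure(
    list(rg = rg, rg_se = rg_se,
         rg_p = if (is.finite(rg_se)) p_from_z(rg / rg_se) else NA_real_,
         rho_g = rho_g, rho_g_se = jackknife_se(fx$loo[, 2]),
         h2 = list(trait1 = c(est = h2_1, se = jackknife_se(f1$loo[, 2])),
                   trait2 = c(est = h2_2, se = jackknife_se(f2$loo[, 2]))),
         intercepts = list(
           trait1 = c(est = f1$full[1], se = jackknife_se(f1$loo[, 1])),
           trait2 = c(est = f2$full[1], se = jackknife_se(f2$loo[, 1])),
           bivariate = c(est = fx$full[1], se = jackknife_se(fx$loo[, 1]))),
         M = M, n_blocks = max(blocks), n_snps = M, defined = defined),
    class = "ldsc_rg_result")
}

#' @export
print.ldsc_rg_result <- function(x, ...) {
  cat(sprintf("<ldsc_rg> rg = %.3f (SE %.3f), h2 = %.3f / %.3f, %d SNPs\n",
              x$rg, x$rg_se, x$h2$trait1[["est"]], x$h2$trait2[["est"]],
              x$n_snps))
  invisible(x)
}
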