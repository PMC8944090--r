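subset_harmonised <- function(h, keep) {
  out <- as_tibble(h)[keep, ]
  structure(out, exposure = attr(h, "exposure"), outcome = attr(h, "outcome"),
            outcome_type = attr(h, "outcome_type"),
            audit = attr(h, "audit"), k = sum(keep),
            class = c("harmonised_set", class(out)))
}

#' MR-PRESSO outlier test and correction
#'
#' Residual-sum-of-squares resampling test for horizontal pleiotropy. The
#' observed statistic is `RSS = sum w_i (beta_out_i - beta_exp_i *
#' theta_hat(-i))^2` with leave-one-out IVW slopes and `w_i = se_out_i^-2`.
#' The null distribution is built by parametric simulation of exposure and
#' outcome betas from their sampling normals under the leave-one-out slopes;
#' the global p is `(1 + #[RSS* >= RSS]) / (n_sim + 1)`. Per-SNP outlier
#' p-values compare each SNP's observed residual to its simulated residual
#' distribution, Bonferroni-corrected across SNPs. The outlier-corrected
#' estimate is the IVW on the non-flagged SNPs, and the distortion p compares
#' the resulting shift in the estimate to shifts from removing random
#' same-size SNP subsets.
#'
#' @param h A `harmonised_set` with at least 4 SNPs.
#' @param n_sim Null simulations (default 1000).
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP p.
#' @param seed Integer seed; results are reproducible under it.
#' @param n_distortion Random subset removals for the distortion test.
#' @return A `presso_result` list: `rss_obs, global_p, snp_p` (tibble with
#'   adjusted p and flags), `outliers`, `corrected` (an `mr_result`, `NULL`
#'   when nothing is flagged, flagged `all_outliers` when everything is),
#'   `distortion_p, n_sim, seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1L,
                      n_distortion = 1000) {
  k <- nrow(h)
  if (k < 4) abort("mr_presso needs k >= 4")
  w <- 1 / h$se_out^2
  be <- h$beta_exp
  bo <- h$beta_out
  num <- sum(w * be * bo)
  den <- sum(w * be^2)
  theta_loo <- (num - w * be * bo) / (den - w * be^2)
  res_obs <- w * (bo - be * theta_loo)^2
  rss_obs <- sum(res_obs)

  with_seed(child_seed(seed, "presso_sim"), {
    BE <- matrix(rnorm(k * n_sim, be, h$se_exp), nrow = k)
    BO <- matrix(rnorm(k * n_sim, be * theta_loo, h$se_out), nrow = k)
  })
  num_s <- colSums(w * BE * BO)
  den_s <- colSums(w * BE^2)
  theta_s <- (matrix(num_s, k, n_sim, byrow = TRUE) - w * BE * BO) /
    (matrix(den_s, k, n_sim, byrow = TRUE) - w * BE^2)
  res_sim <- w * (BO - BE * theta_s)^2
  rss_sim <- colSums(res_sim)
  global_p <- p_empirical(sum(rss_sim >= rss_obs), n_sim)

  p_snp <- vapply(seq_len(k), function(i) {
    p_empirical(sum(res_sim[i, ] >= res_obs[i]), n_sim)
  }, numeric(1))
  p_adj <- pmin(1, p_snp * k)
  is_outlier <- p_adj < outlier_alpha
  snp_p <- tibble(snp = h$snp, residual = res_obs, p = p_snp, p_adj = p_adj,
                  outlier = is_outlier)

  full_ivw <- mr_ivw(h)
  n_out <- sum(is_outlier)
  corrected <- NULL
  distortion_p <- NA_real_
  if (n_out == k) {
    corrected <- skipped_result("ivw_presso_corrected", h, "all SNPs flagged")
  } else if (n_out > 0) {
    corrected <- mr_ivw(subset_harmonised(h, !is_outlier))
    corrected$method <- "ivw_presso_corrected"
    d_obs <- (corrected$estimate - full_ivw$estimate) / abs(full_ivw$estimate)
    with_seed(child_seed(seed, "presso_distortion"), {
      d_rand <- vapply(seq_len(n_distortion), function(b) {
        drop <- sample.int(k, n_out)
        est <- mr_ivw(subset_harmonised(h, !seq_len(k) %in% drop))$estimate
        (est - full_ivw$estimate) / abs(full_ivw$estimate)
      }, numeric(1))
    })
    distortion_p <- p_empirical(sum(abs(d_rand) >= abs(d_obs)), n_distortion)
  }
  structure(list(rss_obs = rss_obs, global_p = global_p, snp_p = snp_p,
                 outliers = h$snp[is_outlier], corrected = corrected,
                 full = full_ivw, distortion_p = distortion_p,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global p = %.4g, %d outlier(s)\n",
              x$global_p, length(x$outliers)))
  invisible(x)
}

#' MR Steiger directionality test
#'
#' Compares the variance the instrument explains in the exposure versus the
#' outcome. Per-SNP r-squared comes from the t-statistic transform
#' `r2 = t^2 / (t^2 + n - 2)` (works for raw or standardised statistics; the
#' `2*eaf*(1-eaf)*beta^2` alternative is available via `r2_method`),
#' aggregated by summing over instruments. The test statistic is a z on the
#' difference of Fisher-transformed correlations with the respective sample
#' sizes.
#'
#' @param h A `harmonised_set` (k >= 1).
#' @param n_exposure,n_outcome GWAS sample sizes (> 2; defaults: medians of
#'   the harmonised `n` columns are not stored, so these are required).
#' @param r2_method `"tstat"` (default) or `"eaf"`.
#' @return A `steiger_result` list: `r2_exposure, r2_outcome,
#'   direction_correct, z, p, snp_direction` (per-SNP flags tibble).
#' @export
steiger <- function(h, n_exposure, n_outcome, r2_method = c("tstat", "eaf")) {
  r2_method <- match.arg(r2_method)
  if (nrow(h) < 1) abort("steiger needs k >= 1")
  if (n_exposure <= 2 || n_outcome <= 2) abort("sample sizes must exceed 2")
  if (r2_method == "tstat") {
    t_exp <- h$beta_exp / h$se_exp
    t_out <- h$beta_out / h$se_out
    r2_exp <- t_exp^2 / (t_exp^2 + n_exposure - 2)
    r2_out <- t_out^2 / (t_out^2 + n_outcome - 2)
  } else {
    r2_exp <- 2 * h$eaf_exp * (1 - h$eaf_exp) * h$beta_exp^2
    r2_out <- 2 * h$eaf_out * (1 - h$eaf_out) * h$beta_out^2
  }
  agg_exp <- min(sum(r2_exp), 1 - 1e-12)
  agg_out <- min(sum(r2_out), 1 - 1e-12)
  z <- (atanh(sqrt(agg_exp)) - atanh(sqrt(agg_out))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  structure(
    list(r2_exposure = agg_exp, r2_outcome = agg_out,
         direction_correct = agg_exp > agg_out, z = z, p = p_from_z(z),
         snp_direction = tibble(snp = h$snp, r2_exp = r2_exp, r2_out = r2_out,
                                correct = r2_exp > r2_out)),
    class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> r2_exp = %.4g, r2_out = %.4g, correct = %s (p = %.3g)\n",
              x$r2_exposure, x$r2_outcome, x$direction_correct, x$p))
  invisible(x)
}

#' Steiger filtering
#'
#' Retains only SNPs whose per-SNP exposure r-squared exceeds the outcome
#' r-squared; re-running the IVW downstream is the caller's responsibility.
#'
#' @inheritParams steiger
#' @return A `harmonised_set`; removed SNPs are appended to the audit
#'   attribute with reason `dropped_steiger`. Attribute `all_removed` is set
#'   when nothing survives.
#' @export
steiger_filter <- function(h, n_exposure, n_outcome,
                           r2_method = c("tstat", "eaf")) {
  st <- steiger(h, n_exposure, n_outcome, r2_method)
  keep <- st$snp_direction$correct
  out <- subset_harmonised(h, keep)
  removed <- as_tibble(h)[!keep, ]
  if (nrow(removed)) removed$action <- "dropped_steiger"
  attr(out, "audit") <- bind_rows(attr(h, "audit"), removed)
  attr(out, "all_removed") <- !any(keep)
  out
}

#' Multivariable inverse-variance-weighted MR
#'
#' Weighted regression of outcome betas on the matrix of exposure betas with
#' no intercept and weights `1/se_out^2`, over the union of the per-exposure
#' instruments, harmonised jointly to the first exposure's orientation. SEs
#' carry the same multiplicative random-effects floor as [mr_ivw()] with
#' residual df `k - n_exposures`. An exposure whose betas are all zero is
#' dropped with a note (its estimate is `NA`); any other rank deficiency is
#' an error.
#'
#' @param exposures Named list of [sumstats()] tibbles (>= 2 for a genuinely
#'   multivariable fit; 1 reduces exactly to [mr_ivw()]).
#' @param outcome A [sumstats()] tibble.
#' @param instruments Character vector of instrument SNP ids (typically the
#'   union of per-exposure instrument sets).
#' @return A tibble with one row per exposure: `exposure, outcome, method,
#'   nsnp, b, se, lo_ci, up_ci, p`.
#' @export
mvmr_ivw <- function(exposures, outcome, instruments) {
  if (!is.list(exposures) || length(exposures) < 1) {
    abort("`exposures` must be a non-empty list of sumstats")
  }
  nm <- names(exposures) %||%
    vapply(exposures, function(e) attr(e, "trait_id"), character(1))
  if (is.null(names(exposures))) names(exposures) <- nm

  e1 <- exposures[[1]]
  h1 <- harmonise(e1[e1$snp %in% instruments, ], outcome)
  base <- as_tibble(h1)
  B <- matrix(NA_real_, nrow = nrow(base), ncol = length(exposures),
              dimnames = list(base$snp, nm))
  B[, 1] <- base$beta_exp
  for (j in seq_along(exposures)[-1]) {
    ej <- as_tibble(exposures[[j]])
    idx <- match(base$snp, ej$snp)
    ej <- ej[idx, ]
    same <- ej$ea == base$ea & ej$oa == base$oa
    swap <- ej$ea == base$oa & ej$oa == base$ea
    B[, j] <- ifelse(same, ej$beta, ifelse(swap, -ej$beta, NA_real_))
  }
  keep <- stats::complete.cases(B)
  B <- B[keep, , drop = FALSE]
  base <- base[keep, ]
  k <- nrow(B)
  if (k < length(exposures) + 1) abort("too few jointly harmonised SNPs")

  zero_col <- apply(B, 2, function(col) all(col == 0))
  use <- which(!zero_col)
  if (length(use) == 0) abort("all exposure beta columns are zero")
  Bu <- B[, use, drop = FALSE]
  if (qr(Bu)$rank < ncol(Bu)) abort("exposure-beta matrix is rank-deficient")

  w <- 1 / base$se_out^2
  XtWX <- crossprod(Bu * sqrt(w))
  cf <- solve(XtWX, crossprod(Bu, w * base$beta_out))
  resid <- base$beta_out - Bu %*% cf
  df <- k - ncol(Bu)
  Q <- sum(w * resid^2)
  infl <- if (df > 0) max(1, sqrt(Q / df)) else 1
  se <- sqrt(diag(solve(XtWX))) * infl

  b_full <- se_full <- setNames(rep(NA_real_, length(exposures)), nm)
  b_full[use] <- as.numeric(cf)
  se_full[use] <- se
  tibble(exposure = nm, outcome = attr(outcome, "trait_id") %||% NA_character_,
         method = "mvmr_ivw", nsnp = k, b = unname(b_full),
         se = unname(se_full),
         lo_ci = unname(b_full - ci_mult * se_full),
         up_ci = unname(b_full + ci_mult * se_full),
         p = p_from_z(b_full / se_full))
}
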