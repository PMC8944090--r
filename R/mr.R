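#' @rdname mr_ivw
#' @param method,estimate,se,k,... Internal constructor fields.
#' @keywords internal
new_mr_result <- function(method, estimate = NA_real_, se = NA_real_,
                          k = 0L, skipped = FALSE, h = NULL, ...) {
  estimate <- unname(estimate)
  se <- unname(se)
  res <- list(method = method,
              exposure = if (!is.null(h)) attr(h, "exposure"),
              outcome = if (!is.null(h)) attr(h, "outcome"),
              outcome_type = if (!is.null(h)) attr(h, "outcome_type"),
              estimate = estimate, se = se,
              ci_lower = estimate - ci_mult * se,
              ci_upper = estimate + ci_mult * se,
              p = p_from_z(estimate / se),
              k = k, skipped = skipped, ...)
  structure(res, class = "mr_result")
}

skipped_result <- function(method, h, reason) {
  new_mr_result(method, k = nrow(h), skipped = TRUE, h = h, notes = reason)
}

#' @export
print.mr_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("<mr_result> %s: skipped (%s)\n", x$method, x$notes))
  } else {
    cat(sprintf("<mr_result> %s: %s -> %s, b = %.4f (SE %.4f, p = %.3g, k = %d)\n",
                x$method, x$exposure %||% "?", x$outcome %||% "?",
                x$estimate, x$se, x$p, x$k))
  }
  invisible(x)
}

#' Inverse-variance-weighted MR (multiplicative random effects)
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1/se_out^2`, which is algebraically the inverse-variance
#' weighted mean of the Wald ratios. The standard error is multiplied by
#' `max(1, sqrt(Q/(k-1)))` — a multiplicative random-effects model floored at
#' the fixed-effect SE.
#'
#' @param h A `harmonised_set`.
#' @return An `mr_result` (estimate in SD units, or log odds for a binary
#'   outcome) carrying `Q`, `Q_df`, `Q_p`.
#' @export
mr_ivw <- function(h) {
  if (nrow(h) < 2) return(skipped_result("ivw", h, "needs k >= 2"))
  w <- 1 / h$se_out^2
  est <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exp^2))
  Q <- sum(w * (h$beta_out - est * h$beta_exp)^2)
  df <- nrow(h) - 1L
  infl <- max(1, sqrt(Q / df))
  new_mr_result("ivw", est, se_fixed * infl, k = nrow(h), h = h,
                Q = Q, Q_df = df, Q_p = pchisq(Q, df, lower.tail = FALSE))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (ratio_i - estimate)^2` with `w_i = se_ratio_i^-2`; `Q` above
#' `k - 1` flags heterogeneity (a symptom of invalid/pleiotropic
#' instruments).
#'
#' @param h A `harmonised_set`.
#' @param ivw_estimate Pooled estimate to centre on; defaults to the IVW
#'   estimate of `h`.
#' @return List `Q, df, p, heterogeneity` (logical flag `Q > k - 1`).
#' @export
cochran_q <- function(h, ivw_estimate = NULL) {
  if (nrow(h) < 2) abort("cochran_q needs k >= 2")
  ivw_estimate <- ivw_estimate %||% mr_ivw(h)$estimate
  wr <- wald_ratios(h)
  Q <- sum(wr$w * (wr$ratio - ivw_estimate)^2)
  df <- nrow(wr) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE),
       heterogeneity = Q > df)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an
#' intercept, after re-orienting every SNP to a positive exposure beta
#' (required for identifiability of the intercept). The intercept estimates
#' average directional pleiotropy; the slope is the bias-adjusted causal
#' estimate under the InSIDE assumption. SEs are inflated by
#' `max(1, sqrt(Q_egger/(k-2)))`. Also reports `I2_GX`, the
#' no-measurement-error (NOME) diagnostic
#' `max(0, (Q_GX - (k-1))/Q_GX)` with
#' `Q_GX = sum se_exp^-2 (beta_exp - weighted mean)^2`; values below 0.9
#' indicate regression-dilution bias for which [simex_egger()] corrects.
#'
#' @param h A `harmonised_set` with at least 3 SNPs.
#' @return An `mr_result` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `i2_gx`, `Q`, `Q_df`, `Q_p`.
#' @export
mr_egger <- function(h) {
  if (nrow(h) < 3) return(skipped_result("egger", h, "needs k >= 3"))
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * by)
  cf <- solve(XtWX, XtWy)
  resid <- by - X %*% cf
  k <- nrow(h)
  Q <- sum(w * resid^2)
  infl <- max(1, sqrt(Q / (k - 2)))
  covm <- solve(XtWX)
  se <- sqrt(diag(covm)) * infl

  wx <- 1 / h$se_exp^2
  bxb <- weighted.mean(bx, wx)
  Q_gx <- sum(wx * (bx - bxb)^2)
  i2_gx <- max(0, (Q_gx - (k - 1)) / Q_gx)

  new_mr_result("egger", cf[2], se[2], k = k, h = h,
                egger_intercept = cf[1], egger_intercept_se = se[1],
                egger_intercept_p = p_from_z(cf[1] / se[1]),
                i2_gx = i2_gx, Q = Q, Q_df = k - 2L,
                Q_p = pchisq(Q, k - 2, lower.tail = FALSE))
}

#' SIMEX-corrected MR-Egger
#'
#' Simulation extrapolation for the NOME violation: for each `lambda`, the
#' exposure betas are perturbed with `Normal(0, lambda * se_exp^2)` noise
#' `n_boot` times and the refitted Egger slopes averaged; a quadratic in
#' `lambda` is then extrapolated to `lambda = -1` (the no-measurement-error
#' limit). The SE reported is the naive Egger SE (a documented
#' approximation). Deterministic under `seed`.
#'
#' @param h A `harmonised_set` with at least 3 SNPs.
#' @param lambdas Perturbation multipliers (>= 3 distinct values including 0).
#' @param n_boot Perturbation replicates per lambda.
#' @param seed Integer seed.
#' @return An `mr_result` with `naive_estimate` and the per-lambda means in
#'   `simex_path`.
#' @export
simex_egger <- function(h, lambdas = c(0, 0.5, 1, 1.5, 2), n_boot = 1000,
                        seed = 1L) {
  if (nrow(h) < 3) return(skipped_result("egger_simex", h, "needs k >= 3"))
  if (length(unique(lambdas)) < 3) abort("need >= 3 distinct lambdas")
  naive <- mr_egger(h)
  egger_slope_int <- function(bx, by, w) {
    flip <- sign(bx); flip[flip == 0] <- 1
    X <- cbind(1, bx * flip)
    cf <- solve(crossprod(X * sqrt(w)), crossprod(X, w * (by * flip)))
    c(cf[1], cf[2])
  }
  w <- 1 / h$se_out^2
  with_seed(seed, {
    means <- vapply(lambdas, function(lam) {
      if (lam == 0) {
        egger_slope_int(h$beta_exp, h$beta_out, w)
      } else {
        sims <- vapply(seq_len(n_boot), function(b) {
          bx <- h$beta_exp + rnorm(nrow(h), 0, sqrt(lam) * h$se_exp)
          egger_slope_int(bx, h$beta_out, w)
        }, numeric(2))
        rowMeans(sims)
      }
    }, numeric(2))
  })
  extrap <- function(vals) {
    fit <- lm(vals ~ lambdas + I(lambdas^2))
    unname(predict(fit, newdata = data.frame(lambdas = -1)))
  }
  est <- extrap(means[2, ])
  intc <- extrap(means[1, ])
  new_mr_result("egger_simex", est, naive$se, k = nrow(h), h = h,
                egger_intercept = intc,
                naive_estimate = naive$estimate, i2_gx = naive$i2_gx,
                simex_path = tibble(lambda = lambdas, slope = means[2, ],
                                    intercept = means[1, ]))
}

# interpolated weighted median of ratios at cumulative standardised weight 0.5
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ws <- w[ord] / sum(w)
  s <- cumsum(ws) - ws / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR
#'
#' Consistent when at least half the weight comes from valid instruments.
#' The estimate interpolates the ordered Wald ratios at cumulative
#' standardised weight 0.5 (midpoint convention); the SE is a parametric
#' bootstrap (betas resampled from their sampling normals).
#'
#' @param h A `harmonised_set` with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return An `mr_result`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  if (nrow(h) < 3) return(skipped_result("weighted_median", h, "needs k >= 3"))
  wr <- wald_ratios(h)
  est <- weighted_median_point(wr$ratio, wr$w)
  boots <- boot_estimates(h, n_boot, seed, function(bx, by, se_out) {
    ratio <- by / bx
    weighted_median_point(ratio, (bx / se_out)^2)
  })
  new_mr_result("weighted_median", est, sd(boots), k = nrow(h), h = h)
}

#' Weighted-mode MR
#'
#' The mode of the Gaussian-kernel weighted density of the Wald ratios
#' (plurality-valid assumption). Bandwidth is `bandwidth_factor` times the
#' modified Silverman rule `0.9 * min(sd, mad) * k^(-1/5)` on the ratios; SE
#' by parametric bootstrap.
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor Multiplier on the Silverman bandwidth (default 1).
#' @return An `mr_result`.
#' @export
weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  if (nrow(h) < 3) return(skipped_result("weighted_mode", h, "needs k >= 3"))
  wr <- wald_ratios(h)
  est <- weighted_mode_point(wr$ratio, wr$w, bandwidth_factor)
  boots <- boot_estimates(h, n_boot, seed, function(bx, by, se_out) {
    ratio <- by / bx
    weighted_mode_point(ratio, (bx / se_out)^2, bandwidth_factor)
  })
  new_mr_result("weighted_mode", est, sd(boots), k = nrow(h), h = h)
}

weighted_mode_point <- function(ratio, w, bandwidth_factor = 1) {
  spread <- min(sd(ratio), mad(ratio))
  if (spread == 0) spread <- sd(ratio)
  if (spread == 0) return(ratio[1])  # degenerate: all ratios equal
  bw <- bandwidth_factor * 0.9 * spread * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, ratio, bw)), numeric(1))
  grid[which.max(dens)]
}

boot_estimates <- function(h, n_boot, seed, point_fun) {
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- rnorm(nrow(h), h$beta_out, h$se_out)
      bx[bx == 0] <- 1e-300
      point_fun(bx, by, h$se_out)
    }, numeric(1))
  })
}

#' Mean F statistic of a genetic instrument
#'
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)` from the aggregate variance
#' explained `r2`, the exposure GWAS sample size `n` and the instrument count
#' `k`. Values above 10 are conventionally taken as strong instruments.
#'
#' @param r2_total Aggregate variance explained by the instrument, in
#'   `[0, 1)`.
#' @param n Exposure sample size (`n > k + 1`).
#' @param k Number of instrument SNPs (>= 1).
#' @return The mean F statistic (scalar).
#' @export
mean_f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) abort("r2_total must be in [0, 1)")
  if (k < 1) abort("k must be >= 1")
  if (n <= k + 1) abort("n must exceed k + 1")
  (r2_total / (1 - r2_total)) * ((n - k - 1) / k)
}
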