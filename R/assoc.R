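#' Rank-based inverse normal transformation
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))` with average ranks for ties.
#' Used for positively skewed traits (e.g. lifetime number of sexual
#' partners) before association scanning.
#'
#' @param values Numeric vector; `NA`s are preserved.
#' @return Transformed vector of the same length.
#' @export
rank_inverse_normal <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("need at least 3 non-missing values")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Per-SNP association scan
#'
#' Continuous traits: ordinary least squares of trait on dosage plus
#' covariates, one SNP at a time (via Frisch-Waugh residualisation, so the
#' scan is a single matrix product). Binary traits: per-SNP logistic
#' regression; betas are log odds. Two-sided p-values come from the normal
#' (Wald) approximation so that `p` and `beta/se` stay mutually consistent.
#' Individuals with a missing trait or covariate are dropped listwise;
#' monomorphic SNPs are excluded with a logged count.
#'
#' @param panel A `genotype_panel`.
#' @param traits A `trait_table`.
#' @param trait_id Trait to scan.
#' @param covariates Covariate columns of `traits` to adjust for.
#' @return A [sumstats()] tibble; attribute `n_dropped_snps` counts excluded
#'   monomorphic SNPs.
#' @export
run_gwas <- function(panel, traits, trait_id, covariates = c("age", "batch")) {
  types <- attr(traits, "types") %||%
    setNames("continuous", trait_id)
  if (!trait_id %in% names(traits)) abort(sprintf("trait '%s' not found", trait_id))
  y <- traits[[trait_id]]
  covs <- as.matrix(as_tibble(traits)[, covariates, drop = FALSE])
  keep <- !is.na(y) & complete.cases(covs)
  y <- y[keep]
  covs <- covs[keep, , drop = FALSE]
  X <- panel$dosages[keep, , drop = FALSE]
  n <- length(y)

  mono <- apply(X, 2, function(x) var(x) == 0)
  n_dropped <- sum(mono)
  if (n_dropped > 0) {
    message(sprintf("run_gwas: excluded %d monomorphic SNP(s)", n_dropped))
    X <- X[, !mono, drop = FALSE]
  }
  meta <- panel$snp_meta[match(colnames(X), panel$snp_meta$snp), ]
  eaf <- pmin(pmax(colMeans(X) / 2, 1e-4), 1 - 1e-4)

  type <- unname(types[[trait_id]] %||% "continuous")
  if (type == "continuous") {
    D <- cbind(1, covs)
    Q <- qr.Q(qr(D))
    y_res <- y - Q %*% crossprod(Q, y)
    X_res <- X - Q %*% crossprod(Q, X)
    sxx <- colSums(X_res^2)
    sxy <- as.numeric(crossprod(X_res, y_res))
    beta <- sxy / sxx
    rss <- sum(y_res^2) - beta^2 * sxx
    df <- n - ncol(D) - 1L
    # floor keeps exact fits (rss == 0) rather than dropping them as unstable
    se <- pmax(sqrt(pmax(rss, 0) / df / sxx), .Machine$double.xmin)
  } else {
    fits <- lapply(seq_len(ncol(X)), function(j) {
      fit <- suppressWarnings(
        glm.fit(cbind(1, X[, j], covs), y, family = binomial()))
      cf <- fit$coefficients[2]
      # Wald SE from the IRLS weights
      W <- fit$weights
      XtWX <- crossprod(cbind(1, X[, j], covs) * sqrt(W))
      se <- sqrt(diag(solve(XtWX)))[2]
      c(cf, se)
    })
    beta <- vapply(fits, `[`, numeric(1), 1)
    se <- vapply(fits, `[`, numeric(1), 2)
  }
  bad <- !is.finite(se) | se <= 0
  if (any(bad)) {
    message(sprintf("run_gwas: excluded %d SNP(s) with unstable SEs", sum(bad)))
  }
  out <- sumstats(
    tibble(snp = meta$snp, chr = meta$chr, pos = meta$pos, ea = meta$ea,
           oa = meta$oa, eaf = unname(eaf), beta = unname(beta),
           se = unname(se), p = p_from_z(beta / se), n = n)[!bad, ],
    trait_id = trait_id, trait_type = type, units = "raw"
  )
  attr(out, "n_dropped_snps") <- n_dropped + sum(bad)
  out
}

#' Standardise GWAS estimates to SD units
#'
#' With the trait SD known, betas and SEs are divided by it. From summary
#' statistics alone, the standardised effect is recovered from the z-score:
#' `beta_std = z / sqrt(2 * eaf * (1 - eaf) * (n + z^2))` and
#' `se_std = 1 / sqrt(2 * eaf * (1 - eaf) * (n + z^2))`.
#' Already-standardised input is returned unchanged with a warning.
#'
#' @param stats A [sumstats()] tibble for a continuous trait.
#' @param trait_sd Optional known phenotype SD.
#' @return A [sumstats()] tibble with the units flag set to `"sd"`.
#' @export
standardise_sumstats <- function(stats, trait_sd = NULL) {
  if (identical(attr(stats, "units"), "sd")) {
    warn("sumstats already SD-standardised; returning unchanged")
    return(stats)
  }
  if (identical(attr(stats, "trait_type"), "binary")) {
    abort("standardise_sumstats applies to continuous traits")
  }
  out <- as_tibble(stats)
  if (!is.null(trait_sd)) {
    out$beta <- out$beta / trait_sd
    out$se <- out$se / trait_sd
  } else {
    z <- out$beta / out$se
    denom <- sqrt(2 * out$eaf * (1 - out$eaf) * (out$n + z^2))
    out$beta <- z / denom
    out$se <- 1 / denom
  }
  sumstats(out, trait_id = attr(stats, "trait_id"),
           trait_type = attr(stats, "trait_type"), units = "sd")
}

#' Select genome-wide-significant instruments with greedy LD clumping
#'
#' SNPs surviving `p < p_threshold` (strict) are sorted by ascending p (ties
#' broken by chromosome then position); the best is accepted and every
#' unaccepted survivor on the same chromosome within `clump_kb` kilobases and
#' with reference-panel `r^2 >= clump_r2` is discarded; repeat.
#'
#' @param stats A [sumstats()] tibble.
#' @param ld_source A `genotype_panel` providing pairwise dosage r-squared.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @param clump_r2 LD threshold (default `0.001`).
#' @param clump_kb Distance window in kb (default `10000`).
#' @return An `instrument_set` tibble (`snp, chr, pos, p, beta_std, se_std,
#'   r2_contrib`) with attributes `trait_id`, `params`, `r2_total`, `status`
#'   (`"ok"` or `"empty"`). The per-SNP variance explained is
#'   `2 * eaf * (1 - eaf) * beta_std^2`.
#' @export
select_instruments <- function(stats, ld_source, p_threshold = 5e-8,
                               clump_r2 = 0.001, clump_kb = 10000) {
  params <- list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb)
  surv <- as_tibble(stats) |>
    filter(.data$p < p_threshold) |>
    arrange(.data$p, .data$chr, .data$pos)
  if (nrow(surv) == 0) {
    out <- tibble(snp = character(), chr = integer(), pos = integer(),
                  p = numeric(), beta_std = numeric(), se_std = numeric(),
                  r2_contrib = numeric())
    return(structure(out, trait_id = attr(stats, "trait_id"), params = params,
                     r2_total = 0, status = "empty",
                     class = c("instrument_set", class(out))))
  }
  missing_ld <- setdiff(surv$snp, ld_source$snp_meta$snp)
  if (length(missing_ld)) {
    abort(paste("reference panel lacks LD for:",
                paste(head(missing_ld, 5), collapse = ", ")))
  }
  r2 <- panel_r2(ld_source, surv$snp)
  alive <- rep(TRUE, nrow(surv))
  accepted <- logical(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    if (!alive[i]) next
    accepted[i] <- TRUE
    alive[i] <- FALSE
    same_chr <- surv$chr == surv$chr[i]
    near <- abs(surv$pos - surv$pos[i]) <= clump_kb * 1000
    linked <- r2[i, ] >= clump_r2
    alive[alive & same_chr & near & linked] <- FALSE
  }
  kept <- surv[accepted, ]

  z <- kept$beta / kept$se
  if (identical(attr(stats, "units"), "sd")) {
    beta_std <- kept$beta
    se_std <- kept$se
  } else {
    denom <- sqrt(2 * kept$eaf * (1 - kept$eaf) * (kept$n + z^2))
    beta_std <- z / denom
    se_std <- 1 / denom
  }
  out <- tibble(snp = kept$snp, chr = kept$chr, pos = kept$pos, p = kept$p,
                beta_std = beta_std, se_std = se_std,
                r2_contrib = 2 * kept$eaf * (1 - kept$eaf) * beta_std^2)
  structure(out, trait_id = attr(stats, "trait_id"), params = params,
            r2_total = sum(out$r2_contrib), status = "ok",
            class = c("instrument_set", class(out)))
}

#' Split a cohort into two random disjoint halves
#'
#' @param panel A `genotype_panel`.
#' @param traits The matching `trait_table`.
#' @param seed Integer seed; the assignment is deterministic under it.
#' @return A list with elements `a` and `b`, each `list(panel, traits, idx)`;
#'   sizes are `ceiling(n/2)` and `floor(n/2)`.
#' @export
split_cohort <- function(panel, traits, seed = 1L) {
  n <- nrow(traits)
  if (n < 4) abort("need at least 4 individuals to split")
  with_seed(seed, {
    idx_a <- sort(sample.int(n, ceiling(n / 2)))
  })
  idx_b <- setdiff(seq_len(n), idx_a)
  list(
    a = list(panel = subset_panel(panel, idx_a),
             traits = subset_traits(traits, idx_a), idx = idx_a),
    b = list(panel = subset_panel(panel, idx_b),
             traits = subset_traits(traits, idx_b), idx = idx_b)
  )
}

subset_traits <- function(traits, idx) {
  out <- as_tibble(traits)[idx, ]
  structure(out, truth = attr(traits, "truth"), types = attr(traits, "types"),
            config = attr(traits, "config"),
            class = c("trait_table", class(out)))
}
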