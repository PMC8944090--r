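#' Simulate causally linked traits over a genotype panel
#'
#' Traits are generated in topological order of the causal DAG. Each trait is
#' the sum of (i) a polygenic component from its own direct-effect SNPs,
#' scaled so the realised genetic variance equals the configured `h2`; (ii)
#' direct causal contributions `theta * upstream trait`; (iii) a loading on a
#' shared standard-normal confounder (the childhood body size analogue); (iv)
#' optional injected horizontal pleiotropy; and (v) independent Gaussian noise
#' sized so the realised trait variance is 1. Binary traits are dichotomised
#' by thresholding the unit-variance liability at the configured prevalence.
#'
#' Direct-effect SNPs are drawn without replacement from the panel, so traits
#' have disjoint causal SNP sets unless pleiotropy is injected.
#'
#' @param panel A `genotype_panel`.
#' @param config A [causal_config()].
#' @return A tibble (class `trait_table`) with columns `id`, covariates `age`
#'   and `batch`, and one column per trait. Attributes: `truth` (list with
#'   `direct` and `total` per-SNP effect tibbles on the dosage scale,
#'   liability scale for binary traits), `types`, `config`.
#' @export
simulate_traits <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "causal_config"))
  X <- panel$dosages
  n <- nrow(X)
  m <- ncol(X)
  ids <- config$traits$trait
  types <- setNames(config$traits$type, ids)
  need <- sum(config$n_snps_per_trait[ids])
  if (need > m) {
    abort(sprintf("panel has %d SNPs but config needs %d direct-effect SNPs",
                  m, need))
  }

  with_seed(child_seed(config$seed, "traits"), {
    # disjoint direct-SNP assignment
    pool <- sample.int(m)
    assign <- list()
    offset <- 0L
    for (t in ids) {
      k <- config$n_snps_per_trait[[t]]
      assign[[t]] <- pool[offset + seq_len(k)]
      offset <- offset + k
    }

    C <- rnorm(n)                       # shared confounder
    age <- rnorm(n)
    batch <- rbinom(n, 1L, 0.5)

    direct <- matrix(0, nrow = m, ncol = length(ids),
                     dimnames = list(colnames(X), ids))
    Y <- matrix(NA_real_, nrow = n, ncol = length(ids),
                dimnames = list(NULL, ids))
    liab <- Y

    for (t in config$topo_order) {
      sys <- numeric(n)
      k <- config$n_snps_per_trait[[t]]
      if (k > 0 && config$h2[[t]] > 0) {
        snps <- assign[[t]]
        b <- rnorm(k)
        g <- X[, snps, drop = FALSE] %*% b
        sdg <- sd(g)
        if (sdg > 0) {
          b <- b * sqrt(config$h2[[t]]) / sdg
          g <- g * sqrt(config$h2[[t]]) / sdg
        }
        direct[snps, t] <- b
        sys <- sys + as.numeric(g)
      }
      edges <- config$theta[config$theta$to == t, , drop = FALSE]
      for (i in seq_len(nrow(edges))) {
        src <- edges$from[i]
        src_val <- if (types[[src]] == "binary") Y[, src] else liab[, src]
        sys <- sys + edges$theta[i] * src_val
      }
      sys <- sys + config$confounder_gamma[[t]] * C
      if (types[[t]] == "continuous") {
        sys <- sys + config$covariate_effects$age * age +
          config$covariate_effects$batch * batch
      }
      pl <- config$pleiotropy
      if (!is.null(pl) && identical(pl$target, t)) {
        src_snps <- assign[[pl$source_trait]][seq_len(pl$n_snps)]
        mu <- if (isTRUE(pl$balanced)) 0 else pl$mean_effect
        delta <- rnorm(pl$n_snps, mu, pl$sd_effect)
        direct[src_snps, t] <- direct[src_snps, t] + delta
        sys <- sys + as.numeric(X[, src_snps, drop = FALSE] %*% delta)
      }
      sys <- sys - mean(sys)   # traits are mean-zero; keeps the liability
                               # threshold on the configured prevalence
      v_sys <- var(sys)
      if (v_sys > 1) {
        abort(sprintf(
          "variance budget exceeded for '%s': realised systematic variance %.3f > 1",
          t, v_sys))
      }
      liab[, t] <- sys + rnorm(n, sd = sqrt(1 - v_sys))
      if (types[[t]] == "binary") {
        thr <- qnorm(1 - config$prevalence[[t]])
        Y[, t] <- as.numeric(liab[, t] > thr)
      } else {
        Y[, t] <- liab[, t]
      }
    }

    if (config$missingness > 0) {
      mask <- matrix(runif(n * length(ids)) < config$missingness,
                     nrow = n)
      Y[mask] <- NA_real_
    }

    # total marginal per-SNP effects through the DAG (liability scale for
    # binary traits): total = direct %*% t(solve(I - Theta))
    p <- length(ids)
    Theta <- matrix(0, p, p, dimnames = list(ids, ids))
    for (i in seq_len(nrow(config$theta))) {
      Theta[config$theta$to[i], config$theta$from[i]] <- config$theta$theta[i]
    }
    Tm <- solve(diag(p) - Theta)        # Tm[t, s] = total effect of s on t
    total <- direct %*% t(Tm)
    colnames(total) <- ids

    out <- tibble(id = seq_len(n), age = age, batch = batch)
    for (t in ids) out[[t]] <- Y[, t]
    truth <- list(
      direct = effects_long(direct, panel),
      total  = effects_long(total, panel),
      assign = assign
    )
    structure(out, truth = truth, types = types, config = config,
              class = c("trait_table", class(out)))
  })
}

effects_long <- function(mat, panel) {
  keep <- which(mat != 0, arr.ind = TRUE)
  tibble(
    snp   = rownames(mat)[keep[, 1]],
    trait = colnames(mat)[keep[, 2]],
    beta  = mat[keep]
  )
}

#' Simulate a genetically correlated pair of polygenic traits
#'
#' Infinitesimal-model companion to [simulate_traits()] for genetic
#' correlation studies: every panel SNP is causal for both traits with
#' bivariate-normal standardized effects correlated at `rg`, genetic
#' components scaled to the requested heritabilities, and environmental
#' deviations correlated at `env_corr` (shared-environment analogue; with
#' full sample overlap the LDSC bivariate intercept picks up
#' `rg * sqrt(h2_1 h2_2) + env_corr * sqrt((1-h2_1)(1-h2_2))`).
#'
#' @param panel A `genotype_panel`.
#' @param h2 Length-2 vector of heritabilities in `[0, 1)`.
#' @param rg Genetic correlation of the per-SNP effects in `[-1, 1]`.
#' @param env_corr Correlation of the environmental components.
#' @param seed Integer seed.
#' @return A `trait_table` with traits `t1`, `t2` (both continuous).
#' @export
simulate_trait_pair <- function(panel, h2 = c(0.3, 0.3), rg = 0.5,
                                env_corr = 0, seed = 1L) {
  stopifnot(length(h2) == 2, all(h2 >= 0 & h2 < 1), abs(rg) <= 1,
            abs(env_corr) <= 1)
  X <- panel$dosages
  n <- nrow(X)
  m <- ncol(X)
  with_seed(seed, {
    B <- matrix(rnorm(m * 2), ncol = 2)
    B[, 2] <- rg * B[, 1] + sqrt(1 - rg^2) * B[, 2]
    Xs <- scale(X)
    E <- matrix(rnorm(n * 2), ncol = 2)
    E[, 2] <- env_corr * E[, 1] + sqrt(1 - env_corr^2) * E[, 2]
    out <- tibble(id = seq_len(n), age = rnorm(n), batch = rbinom(n, 1L, 0.5))
    direct <- matrix(0, m, 2, dimnames = list(colnames(X), c("t1", "t2")))
    for (j in 1:2) {
      g <- as.numeric(Xs %*% B[, j])
      if (h2[j] > 0) g <- g * sqrt(h2[j]) / sd(g) else g <- g * 0
      out[[paste0("t", j)]] <- g + sqrt(1 - h2[j]) * E[, j]
      direct[, j] <- if (h2[j] > 0) B[, j] * sqrt(h2[j]) / sd(Xs %*% B[, j]) else 0
    }
    truth <- list(direct = effects_long(direct, panel),
                  total = effects_long(direct, panel))
    structure(out, truth = truth,
              types = c(t1 = "continuous", t2 = "continuous"),
              config = NULL, class = c("trait_table", class(out)))
  })
}

#' Ground-truth per-SNP effects of a simulated trait table
#'
#' @param traits A `trait_table` from [simulate_traits()].
#' @param which `"total"` (marginal effects through the DAG, the quantity a
#'   GWAS estimates) or `"direct"`.
#' @return Tibble `snp, trait, beta`.
#' @export
true_effects <- function(traits, which = c("total", "direct")) {
  which <- match.arg(which)
  attr(traits, "truth")[[which]]
}
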