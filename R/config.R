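#' Trait registry for the reproductive-factor analogues
#'
#' The eight traits the simulator and study pipeline know about, with their
#' type and the temporal ordering used to build the default pair plan:
#' menarche precedes age at first sexual intercourse (AFS), which precedes age
#' at first birth (AFB) and lifetime number of sexual partners; AFB precedes
#' age at last birth (ALB), which precedes menopause.
#'
#' @return A tibble with columns `trait`, `label`, `type` (continuous/binary)
#'   and `n_gwas` (the per-trait UK Biobank GWAS sample size, used as
#'   the default reporting `n`).
#' @export
trait_registry <- function() {
  tibble(
    trait  = c("menarche", "afs", "afb", "alb", "menopause",
               "n_births", "partners", "parous"),
    label  = c("Age at menarche", "Age first had sexual intercourse",
               "Age at first live birth", "Age at last live birth",
               "Age at menopause", "Number of live births",
               "Lifetime number of sexual partners", "Ever parous status"),
    type   = c(rep("continuous", 7), "binary"),
    n_gwas = c(243898L, 219486L, 203606L, 203356L, 143791L,
               250746L, 208274L, 250746L)
  )
}

#' Default temporal partial order over the trait registry
#'
#' Edges (earlier, later). Transitive closure is taken when the pair plan is
#' built, so only covering relations are listed.
#'
#' @return A tibble with columns `earlier`, `later`.
#' @export
default_temporal_order <- function() {
  tibble(
    earlier = c("menarche", "afs", "afs", "afb", "alb"),
    later   = c("afs", "afb", "partners", "alb", "menopause")
  )
}

# headline total (marginal) causal effects, SD units; binary target effects on
# the liability scale as log odds ratios
default_total_effects <- function() {
  tibble(
    from = c("menarche", "menarche", "menarche", "menarche",
             "afs", "afs", "afs", "afs", "afs", "afs",
             "afb", "afb", "afb", "alb", "partners"),
    to   = c("afs", "afb", "alb", "menopause",
             "menopause", "afb", "alb", "n_births", "partners", "parous",
             "menopause", "alb", "n_births", "n_births", "parous"),
    beta = c(0.09, 0.07, 0.06, 0.06,
             0.11, 0.56, 0.42, -0.24, -0.51, log(0.90),
             0.21, 0.72, -0.38, -0.19, log(0.96))
  )
}

#' Default direct-edge effects implied by the headline total effects
#'
#' Published MR estimates are total (marginal) effects; the simulator needs
#' direct DAG edges. With traits in topological order and `T` the matrix of
#' total effects (identity on the diagonal), the direct-effect matrix is
#' `Theta = I - solve(T)`. Entries below 1e-10 in absolute value are dropped.
#'
#' @return A tibble with columns `from`, `to`, `theta` (direct effect, SD
#'   units per SD of the source trait).
#' @export
default_theta <- function() {
  traits <- trait_registry()$trait
  totals <- default_total_effects()
  p <- length(traits)
  Tm <- diag(p)
  dimnames(Tm) <- list(traits, traits)
  for (i in seq_len(nrow(totals))) {
    Tm[totals$to[i], totals$from[i]] <- totals$beta[i]
  }
  Theta <- diag(p) - solve(Tm)
  idx <- which(abs(Theta) > 1e-10, arr.ind = TRUE)
  tibble(
    from  = traits[idx[, 2]],
    to    = traits[idx[, 1]],
    theta = Theta[idx]
  ) |> arrange(match(.data$to, traits), match(.data$from, traits))
}

#' Build the causal configuration for the synthetic cohort generator
#'
#' Describes the stated world the generator draws from: the per-trait
#' polygenic architecture, the direct causal edges between traits, loadings on
#' a shared confounder (a childhood body size analogue), optional horizontal
#' pleiotropy injected into instrument SNPs, and the liability-threshold
#' prevalence of binary traits.
#'
#' @param traits Trait registry tibble (`trait`, `type`, optionally `label`,
#'   `n_gwas`); defaults to [trait_registry()].
#' @param n_snps_per_trait Number of direct-effect SNPs per trait. A single
#'   count or a named vector over traits. Default 30 (desk-scale; the
#'   published instrument counts range 4-223 at biobank sample sizes).
#' @param h2 Named vector of SNP heritabilities in `[0, 1)`.
#' @param theta Tibble of direct causal edges (`from`, `to`, `theta`); must be
#'   acyclic. Defaults to [default_theta()].
#' @param confounder_gamma Named vector of loadings on the shared confounder.
#' @param pleiotropy List with `n_snps`, `mean_effect`, `sd_effect`,
#'   `balanced`, `target`: direct SNP->target effects added to the first
#'   `n_snps` instrument SNPs of `source_trait` (see [simulate_traits()]).
#'   `NULL` for none.
#' @param prevalence Named vector of binary-trait population prevalences in
#'   `(0, 1)`. Default: ever-parous 0.8131 (never-parous fraction 18.69%).
#' @param missingness Missing-at-random rate applied to trait values.
#' @param covariate_effects Named list with `age` and `batch` loadings on
#'   continuous traits (defaults 0: covariates present but inert).
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @return An object of class `causal_config`.
#' @export
causal_config <- function(traits = trait_registry(),
                          n_snps_per_trait = 30L,
                          h2 = c(menarche = 0.20, afs = 0.15, afb = 0.15,
                                 alb = 0.10, menopause = 0.15, n_births = 0.06,
                                 partners = 0.10, parous = 0.05),
                          theta = default_theta(),
                          confounder_gamma = c(menarche = -0.15, afs = -0.05,
                                               afb = -0.05),
                          pleiotropy = NULL,
                          prevalence = c(parous = 0.8131),
                          missingness = 0,
                          covariate_effects = list(age = 0, batch = 0),
                          seed = 1L) {
  traits <- as_tibble(traits)
  if (!all(c("trait", "type") %in% names(traits))) {
    abort("`traits` needs columns `trait` and `type`")
  }
  ids <- traits$trait
  if (anyDuplicated(ids)) abort("duplicate trait ids")

  if (length(n_snps_per_trait) == 1L && is.null(names(n_snps_per_trait))) {
    n_snps_per_trait <- setNames(rep(as.integer(n_snps_per_trait),
                                     length(ids)), ids)
  }
  h2 <- expand_named(h2, ids, default = 0, name = "h2")
  if (any(h2 < 0 | h2 >= 1)) abort("h2 values must lie in [0, 1)")
  confounder_gamma <- expand_named(confounder_gamma, ids, default = 0,
                                   name = "confounder_gamma")

  theta <- as_tibble(theta)
  if (nrow(theta) > 0) {
    bad <- setdiff(unique(c(theta$from, theta$to)), ids)
    if (length(bad)) abort(paste("theta refers to unknown traits:",
                                 paste(bad, collapse = ", ")))
    if (any(theta$from == theta$to)) abort("theta contains a self-loop")
  }
  order <- topological_order(ids, theta)  # errors on cycles

  binary <- traits$trait[traits$type == "binary"]
  prevalence <- prevalence[names(prevalence) %in% ids]
  missing_prev <- setdiff(binary, names(prevalence))
  if (length(missing_prev)) {
    abort(paste("no prevalence for binary trait(s):",
                paste(missing_prev, collapse = ", ")))
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("prevalence must lie in (0, 1)")
  }

  # theoretical variance budget check, treating upstream traits as unit
  # variance (the simulator additionally balances the realised noise variance)
  for (t in ids) {
    th <- theta$theta[theta$to == t]
    budget <- h2[[t]] + confounder_gamma[[t]]^2 + sum(th^2)
    if (budget > 1) {
      abort(sprintf(
        "variance budget exceeded for '%s': h2 + gamma^2 + sum(theta^2) = %.3f > 1",
        t, budget))
    }
  }
  if (missingness < 0 || missingness >= 1) abort("missingness must be in [0, 1)")

  structure(
    list(traits = traits, n_snps_per_trait = n_snps_per_trait, h2 = h2,
         theta = theta, confounder_gamma = confounder_gamma,
         pleiotropy = pleiotropy, prevalence = prevalence,
         missingness = missingness, covariate_effects = covariate_effects,
         topo_order = order, seed = as.integer(seed)),
    class = "causal_config"
  )
}

expand_named <- function(x, ids, default, name) {
  out <- setNames(rep(default, length(ids)), ids)
  if (is.null(names(x)) && length(x) == length(ids)) {
    names(x) <- ids
  }
  extra <- setdiff(names(x), ids)
  if (length(extra)) abort(paste0("`", name, "` names unknown traits: ",
                                  paste(extra, collapse = ", ")))
  out[names(x)] <- x
  out
}

# Kahn's algorithm; aborts on a cycle
topological_order <- function(ids, theta) {
  indeg <- setNames(rep(0L, length(ids)), ids)
  for (t in theta$to) indeg[[t]] <- indeg[[t]] + 1L
  order <- character(0)
  avail <- ids[indeg[ids] == 0L]
  indeg_work <- indeg
  edges <- theta
  while (length(avail)) {
    v <- avail[[1]]
    avail <- avail[-1]
    order <- c(order, v)
    out_edges <- edges$to[edges$from == v]
    edges <- edges[edges$from != v, , drop = FALSE]
    for (w in out_edges) {
      indeg_work[[w]] <- indeg_work[[w]] - 1L
      if (indeg_work[[w]] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) != length(ids)) abort("theta edges contain a cycle")
  order
}

#' @export
print.causal_config <- function(x, ...) {
  cat("<causal_config>\n")
  cat("  traits:", paste(x$traits$trait, collapse = ", "), "\n")
  cat("  direct edges:", nrow(x$theta), " | seed:", x$seed, "\n")
  invisible(x)
}
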