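#' Construct a GWAS summary-statistics table
#'
#' The central tabular currency of the package: one row per SNP with effect
#' estimates on the effect-allele (`ea`) dosage scale.
#'
#' @param x A data frame with columns `snp, chr, pos, ea, oa, eaf, beta, se,
#'   p, n`.
#' @param trait_id Trait label.
#' @param trait_type `"continuous"` or `"binary"` (binary betas are log odds).
#' @param units `"raw"` or `"sd"` (SD-standardised).
#' @param validate Check invariants (`se > 0`, `p` in `(0, 1]`, `eaf` in
#'   `(0, 1)`, alleles in A/C/G/T, `p` consistent with `beta/se`).
#' @return A tibble of class `sumstats`.
#' @export
sumstats <- function(x, trait_id, trait_type = "continuous", units = "raw",
                     validate = TRUE) {
  cols <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
  x <- as_tibble(x)[, cols]
  out <- structure(x, trait_id = trait_id, trait_type = trait_type,
                   units = units, class = c("sumstats", class(x)))
  if (validate) validate_sumstats(out)
  out
}

validate_sumstats <- function(x) {
  if (any(x$se <= 0)) abort("sumstats: se must be > 0")
  if (any(x$p <= 0 | x$p > 1)) abort("sumstats: p must be in (0, 1]")
  if (any(x$eaf <= 0 | x$eaf >= 1)) abort("sumstats: eaf must be in (0, 1)")
  if (!all(c(x$ea, x$oa) %in% c("A", "C", "G", "T"))) {
    abort("sumstats: alleles must be A/C/G/T")
  }
  pz <- p_from_z(x$beta / x$se)
  ok <- abs(pz - x$p) <= 1e-6 * pmax(pz, x$p) | pz < 1e-300
  if (!all(ok)) abort("sumstats: p inconsistent with beta/se")
  invisible(x)
}

#' @export
`[.sumstats` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "trait_id") <- attr(x, "trait_id")
    attr(out, "trait_type") <- attr(x, "trait_type")
    attr(out, "units") <- attr(x, "units")
    class(out) <- class(x)
  }
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s, %s units), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), attr(x, "units"),
              nrow(x)))
  NextMethod()
}

#' Emit GWAS summary statistics for a simulated trait
#'
#' Two routes to the same output dialect. `"individual"` runs the
#' covariate-adjusted per-SNP regressions of [run_gwas()] on the cohort.
#' `"analytic"` is the fast path for estimator tests: it draws
#' `beta_hat ~ Normal(beta_true, se)` with
#' `se = 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)` (residual SD 1; traits are
#' unit variance by construction), where `beta_true` is the SNP's total
#' marginal effect through the causal DAG. The analytic route treats SNPs as
#' unlinked and, for binary traits, works on the liability scale.
#'
#' @param panel A `genotype_panel`.
#' @param traits A `trait_table` from [simulate_traits()].
#' @param trait_id Trait to emit.
#' @param mode `"analytic"` or `"individual"`.
#' @param n_eff Effective sample size for analytic SEs (>= 10); defaults to
#'   the cohort size.
#' @param seed Seed for the analytic draw (ignored for individual mode).
#' @return A [sumstats()] tibble over all panel SNPs.
#' @export
emit_sumstats <- function(panel, traits, trait_id,
                          mode = c("analytic", "individual"),
                          n_eff = NULL, seed = 1L) {
  mode <- match.arg(mode)
  types <- attr(traits, "types")
  if (!trait_id %in% names(types)) {
    abort(sprintf("unknown trait id '%s'", trait_id))
  }
  if (mode == "individual") {
    return(run_gwas(panel, traits, trait_id))
  }
  n_eff <- n_eff %||% nrow(traits)
  if (n_eff < 10) abort("n_eff must be >= 10")
  meta <- panel$snp_meta
  eaf <- colMeans(panel$dosages) / 2
  eaf <- pmin(pmax(eaf, 1e-4), 1 - 1e-4)
  truth <- true_effects(traits, "total")
  beta_true <- setNames(rep(0, nrow(meta)), meta$snp)
  truth_t <- truth[truth$trait == trait_id, ]
  beta_true[truth_t$snp] <- truth_t$beta
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)
  with_seed(seed, {
    beta_hat <- rnorm(nrow(meta), beta_true, se)
    sumstats(
      tibble(snp = meta$snp, chr = meta$chr, pos = meta$pos,
             ea = meta$ea, oa = meta$oa, eaf = unname(eaf),
             beta = beta_hat, se = unname(se),
             p = p_from_z(beta_hat / se), n = round(n_eff)),
      trait_id = trait_id, trait_type = unname(types[[trait_id]]),
      units = "raw"
    )
  })
}

#' Write summary statistics to the tab-delimited dialect
#'
#' Columns exactly `snp chr pos ea oa eaf beta se p n`, 1-based positions.
#'
#' @param stats A [sumstats()] tibble.
#' @param path Output file.
#' @export
write_sumstats <- function(stats, path) {
  readr::write_tsv(as_tibble(stats)[, c("snp", "chr", "pos", "ea", "oa",
                                        "eaf", "beta", "se", "p", "n")], path)
  invisible(path)
}

#' Read summary statistics from the tab-delimited dialect
#'
#' @param path Input file with columns `snp chr pos ea oa eaf beta se p n`.
#' @inheritParams sumstats
#' @return A [sumstats()] tibble.
#' @export
read_sumstats <- function(path, trait_id, trait_type = "continuous",
                          units = "raw") {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         snp = "c", chr = "i", pos = "i", ea = "c", oa = "c",
                         eaf = "d", beta = "d", se = "d", p = "d", n = "d"))
  sumstats(x, trait_id = trait_id, trait_type = trait_type, units = units)
}
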