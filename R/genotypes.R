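#' Describe the LD-block layout of a synthetic reference panel
#'
#' @param n_blocks Number of independent LD blocks.
#' @param snps_per_block SNPs in each block (recycled).
#' @param rho Within-block latent AR(1) correlation in `[0, 1)` (recycled).
#' @param chr Chromosome assignment per block (recycled).
#' @param maf Optional fixed minor-allele frequency (recycled over SNPs);
#'   `NA` to draw each MAF uniformly from `[0.05, 0.5]`.
#' @return A tibble with one row per block: `block`, `n_snps`, `rho`, `chr`,
#'   `maf`.
#' @export
genotype_blocks <- function(n_blocks, snps_per_block = 10L, rho = 0.6,
                            chr = 1L, maf = NA_real_) {
  tibble(
    block  = seq_len(n_blocks),
    n_snps = rep_len(as.integer(snps_per_block), n_blocks),
    rho    = rep_len(rho, n_blocks),
    chr    = rep_len(as.integer(chr), n_blocks),
    maf    = rep_len(maf, n_blocks)
  )
}

#' Simulate a genotype dosage panel with block-wise LD
#'
#' Genotypes are built from two latent Gaussian haplotypes per individual.
#' Within each block the latent variables follow an AR(1) process with
#' correlation `rho`; each haplotype carries the alternate allele when its
#' latent value falls below the `qnorm(maf)` threshold, so every SNP is in
#' Hardy-Weinberg equilibrium at its MAF and the dosage correlation between
#' neighbouring SNPs is tunable through `rho`. Blocks are mutually
#' independent, which gives clean ground truth for clumping and LD-score
#' tests.
#'
#' @param n Number of individuals (>= 2).
#' @param blocks Block layout tibble from [genotype_blocks()].
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param pos_spacing_bp Base-pair spacing between adjacent SNPs (default
#'   10 kb).
#' @return A `genotype_panel`: list with `dosages` (n x m integer matrix,
#'   columns named by SNP id), `snp_meta` (tibble `snp, chr, pos, ea, oa,
#'   maf, block`), and `block_structure`.
#' @export
simulate_genotypes <- function(n, blocks, seed = 1L, pos_spacing_bp = 10000L) {
  n <- stopifnot_scalar_int(n, "n", min = 2L)
  blocks <- as_tibble(blocks)
  if (any(blocks$rho < 0 | blocks$rho >= 1)) {
    abort("block rho must lie in [0, 1)")
  }
  m <- sum(blocks$n_snps)
  with_seed(seed, {
    mafs <- numeric(m)
    dos <- matrix(0L, nrow = n, ncol = m)
    offset <- 0L
    for (b in seq_len(nrow(blocks))) {
      mb <- blocks$n_snps[b]
      rho <- blocks$rho[b]
      maf_b <- if (is.na(blocks$maf[b])) {
        runif(mb, 0.05, 0.5)
      } else {
        rep(blocks$maf[b], mb)
      }
      thr <- qnorm(maf_b)
      hap <- function() {
        Z <- matrix(rnorm(n * mb), nrow = n, ncol = mb)
        if (mb > 1 && rho > 0) {
          for (j in 2:mb) {
            Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
          }
        }
        Z
      }
      A1 <- sweep(hap(), 2, thr, "<")
      A2 <- sweep(hap(), 2, thr, "<")
      dos[, offset + seq_len(mb)] <- A1 + A2
      mafs[offset + seq_len(mb)] <- maf_b
      offset <- offset + mb
    }
    if (any(mafs < 0.01 | mafs > 0.5)) abort("MAF outside [0.01, 0.5]")

    # random allele pair per SNP (distinct bases; some pairs palindromic)
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, m, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))

    chr <- rep.int(blocks$chr, blocks$n_snps)
    pos <- integer(m)
    for (cc in unique(chr)) {
      idx <- which(chr == cc)
      pos[idx] <- seq_along(idx) * pos_spacing_bp
    }
    snp <- sprintf("rs%d_%d", chr, pos)
    colnames(dos) <- snp

    meta <- tibble(snp = snp, chr = chr, pos = pos, ea = ea, oa = unname(oa),
                   maf = mafs, block = rep.int(blocks$block, blocks$n_snps))
    structure(list(dosages = dos, snp_meta = meta, block_structure = blocks,
                   seed = as.integer(seed)),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " SNPs in ", nrow(x$block_structure), " blocks\n",
      sep = "")
  invisible(x)
}

#' Subset a genotype panel by individuals
#'
#' @param panel A `genotype_panel`.
#' @param idx Integer vector of individual indices to keep.
#' @return A `genotype_panel` restricted to `idx`.
#' @export
subset_panel <- function(panel, idx) {
  panel$dosages <- panel$dosages[idx, , drop = FALSE]
  panel
}

#' Pairwise dosage r-squared between SNPs of a reference panel
#'
#' @param panel A `genotype_panel`.
#' @param snps Optional character vector of SNP ids (default all).
#' @return A symmetric matrix of squared Pearson correlations between dosages.
#' @export
panel_r2 <- function(panel, snps = NULL) {
  X <- panel$dosages
  if (!is.null(snps)) X <- X[, snps, drop = FALSE]
  cor(X)^2
}
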