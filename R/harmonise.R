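#' Harmonise exposure and outcome summary statistics
#'
#' Inner-joins on SNP id and puts the outcome effects on the exposure's
#' effect-allele orientation. Outcome rows whose alleles are swapped relative
#' to the exposure (directly or after strand complement) have their beta
#' negated and eaf complemented. Palindromic SNPs (A/T, G/C) cannot be
#' oriented from alleles alone: they are aligned by allele frequency when
#' both eafs lie outside `0.5 +/- palindrome_eaf_window`, matching sides
#' means already aligned and opposite sides means flip; otherwise the SNP is
#' dropped. Every action is recorded; dropped rows are kept in an audit
#' attribute.
#'
#' @param exposure,outcome [sumstats()] tibbles sharing at least one SNP, or
#'   a `harmonised_set` as `exposure` (returned unchanged, making the
#'   operation idempotent).
#' @param palindrome_eaf_window Half-width of the ambiguity window around
#'   0.5 (default 0.08).
#' @return A `harmonised_set` tibble (`snp, ea, oa, beta_exp, se_exp,
#'   eaf_exp, beta_out, se_out, eaf_out, action`) with attributes `exposure`,
#'   `outcome`, `audit` (dropped rows and reasons), `k`.
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  if (inherits(exposure, "harmonised_set")) return(exposure)
  e <- as_tibble(exposure)
  o <- as_tibble(outcome)
  shared <- intersect(e$snp, o$snp)
  if (length(shared) == 0) abort("exposure and outcome share no SNPs")
  e <- e[match(shared, e$snp), ]
  o <- o[match(shared, o$snp), ]

  pal <- is_palindromic(e$ea, e$oa)
  same <- o$ea == e$ea & o$oa == e$oa
  swap <- o$ea == e$oa & o$oa == e$ea
  flip_same <- allele_complement(o$ea) == e$ea & allele_complement(o$oa) == e$oa
  flip_swap <- allele_complement(o$ea) == e$oa & allele_complement(o$oa) == e$ea

  action <- rep(NA_character_, length(shared))
  flip <- rep(FALSE, length(shared))
  w <- palindrome_eaf_window

  # non-palindromic: alleles identify the orientation
  action[!pal & same] <- "kept"
  action[!pal & flip_same] <- "kept"
  flip[!pal & (swap | flip_swap)] <- TRUE
  action[!pal & (swap | flip_swap)] <- "flipped"
  action[!pal & !(same | swap | flip_same | flip_swap)] <- "dropped_mismatch"

  # palindromic: orientation from allele frequencies
  pal_match <- pal & (same | swap | flip_same | flip_swap)
  action[pal & !pal_match] <- "dropped_mismatch"
  # outcome eaf expressed for the allele it labels ea; for palindromes "swap"
  # and "same" are indistinguishable, so compare frequencies directly
  informative <- abs(e$eaf - 0.5) > w & abs(o$eaf - 0.5) > w
  same_side <- (e$eaf > 0.5) == (o$eaf > 0.5)
  action[pal_match & !informative] <- "dropped_palindromic"
  action[pal_match & informative & same_side] <- "kept"
  flip[pal_match & informative & !same_side] <- TRUE
  action[pal_match & informative & !same_side] <- "flipped"

  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)
  out <- tibble(snp = e$snp, ea = e$ea, oa = e$oa,
                beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
                beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
                action = action)
  kept <- !startsWith(action, "dropped")
  audit <- out[!kept, ]
  out <- out[kept, ]
  structure(out,
            exposure = attr(exposure, "trait_id"),
            outcome = attr(outcome, "trait_id"),
            outcome_type = attr(outcome, "trait_type"),
            audit = audit, k = nrow(out),
            class = c("harmonised_set", class(out)))
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s -> %s, %d SNPs retained (%d dropped)\n",
              attr(x, "exposure") %||% "?", attr(x, "outcome") %||% "?",
              nrow(x), nrow(attr(x, "audit") %||% tibble())))
  NextMethod()
}

#' Per-SNP Wald ratios
#'
#' `ratio = beta_out / beta_exp`, `se = se_out / |beta_exp|` (first-order
#' delta method). SNPs with a zero exposure beta are excluded with a warning.
#'
#' @param h A `harmonised_set`.
#' @return A tibble `snp, ratio, se_ratio, w` (`w = se_ratio^-2`).
#' @export
wald_ratios <- function(h) {
  x <- as_tibble(h)
  zero <- x$beta_exp == 0
  if (any(zero)) {
    warn(sprintf("excluding %d SNP(s) with zero exposure beta", sum(zero)))
    x <- x[!zero, ]
  }
  tibble(snp = x$snp, ratio = x$beta_out / x$beta_exp,
         se_ratio = x$se_out / abs(x$beta_exp),
         w = (x$beta_exp / x$se_out)^2)
}
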