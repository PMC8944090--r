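#' Printed instrument-strength inputs of the UK Biobank reproductive-factor GWAS
#'
#' The per-exposure GWAS sample size, aggregate instrument r-squared and
#' instrument count as printed in the UK Biobank reproductive-factor
#' instrument-strength table,
#' together with the printed mean F statistic. These are inputs for the
#' worked example: [mean_f_statistic()] recomputes each F from (r2, N,
#' nsnps).
#'
#' @return A tibble `trait, n, r2, nsnp, f_printed, r2_digits` where
#'   `r2_digits` is the number of significant digits the r-squared was
#'   printed with (bounds the achievable agreement with `f_printed`).
#' @export
ukb_instrument_strength <- function() {
  tibble(
    trait = c("menarche", "menopause", "afb", "alb", "n_births", "afs",
              "partners", "parous"),
    n = c(243898L, 143791L, 203606L, 203356L, 250746L, 219486L,
          208274L, 250746L),
    r2 = c(0.064, 0.047, 8.38e-3, 1.92e-3, 1.68e-3, 9.44e-3, 6.36e-3,
           8.59e-4),
    nsnp = c(223L, 84L, 41L, 9L, 9L, 53L, 34L, 4L),
    f_printed = c(74.95, 85.08, 41.97, 43.46, 46.75, 39.46, 39.20, 53.92),
    r2_digits = c(2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L)
  )
}
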