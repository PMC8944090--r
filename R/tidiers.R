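#' Tidy an MR result into one row
#'
#' Columns follow the conventional results-table shape:
#' `exposure outcome method nsnp b se lo_ci up_ci p`.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(exposure = x$exposure %||% NA_character_,
         outcome = x$outcome %||% NA_character_,
         method = x$method, nsnp = x$k,
         b = x$estimate, se = x$se, lo_ci = x$ci_lower, up_ci = x$ci_upper,
         p = x$p,
         or = if (identical(x$outcome_type, "binary")) exp(x$estimate)
              else NA_real_,
         egger_intercept = x$egger_intercept %||% NA_real_,
         egger_intercept_p = x$egger_intercept_p %||% NA_real_,
         skipped = x$skipped)
}

#' Model-level diagnostics of an MR result
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble with heterogeneity and NOME diagnostics.
#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = x$method, nsnp = x$k,
         Q = x$Q %||% NA_real_, Q_df = x$Q_df %||% NA_integer_,
         Q_p = x$Q_p %||% NA_real_, i2_gx = x$i2_gx %||% NA_real_)
}

#' @rdname tidy.mr_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble(exposure = x$exposure %||% NA_character_,
         outcome = x$outcome %||% NA_character_,
         method = paste0(x$method, "_meta"), nsnp = NA_integer_,
         b = x$estimate, se = x$se, lo_ci = x$ci_lower, up_ci = x$ci_upper,
         p = x$p, or = NA_real_, egger_intercept = NA_real_,
         egger_intercept_p = NA_real_, skipped = FALSE)
}

#' @rdname glance.mr_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble(method = paste0(x$method, "_meta"), nsnp = NA_integer_,
         Q = x$Q, Q_df = x$Q_df, Q_p = x$Q_p, i2_gx = NA_real_)
}

#' @rdname tidy.mr_result
#' @export
tidy.ldsc_rg_result <- function(x, ...) {
  tibble(rg = x$rg, se = x$rg_se, p = x$rg_p,
         h2_1 = x$h2$trait1[["est"]], h2_1_se = x$h2$trait1[["se"]],
         h2_2 = x$h2$trait2[["est"]], h2_2_se = x$h2$trait2[["se"]],
         intercept_1 = x$intercepts$trait1[["est"]],
         intercept_2 = x$intercepts$trait2[["est"]],
         bivariate_intercept = x$intercepts$bivariate[["est"]],
         n_snps = x$n_snps, defined = x$defined)
}
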