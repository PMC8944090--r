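#' Scatter plot of a harmonised set with fitted MR lines
#'
#' SNP-exposure versus SNP-outcome effects (re-oriented to positive exposure
#' betas) with the IVW line through the origin and, with k >= 3, the MR-Egger
#' line with its intercept.
#'
#' @param object A `harmonised_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.harmonised_set <- function(object, ...) {
  flip <- sign(object$beta_exp)
  flip[flip == 0] <- 1
  df <- tibble(bx = object$beta_exp * flip, by = object$beta_out * flip,
               se_x = object$se_exp, se_y = object$se_out)
  ivw <- mr_ivw(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_y,
                                        ymax = .data$by + .data$se_y),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_x,
                                         xmax = .data$bx + .data$se_x),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$estimate,
                         colour = "#2c7fb8") +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  title = sprintf("%s → %s",
                                  attr(object, "exposure") %||% "exposure",
                                  attr(object, "outcome") %||% "outcome"),
                  subtitle = sprintf("IVW b = %.3f (k = %d)", ivw$estimate,
                                     nrow(object))) +
    ggplot2::theme_minimal()
  if (nrow(object) >= 3) {
    eg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(intercept = eg$egger_intercept,
                                  slope = eg$estimate, colour = "#d95f02",
                                  linetype = "dashed")
  }
  p
}

#' Heatmap of a pairwise genetic-correlation matrix
#'
#' @param rg_matrix The `rg_matrix` tibble of a [run_full_study()] report
#'   (`trait1, trait2, rg`).
#' @return A ggplot object.
#' @export
plot_rg_matrix <- function(rg_matrix) {
  df <- bind_rows(rg_matrix,
                  rename(rg_matrix, trait1 = "trait2", trait2 = "trait1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait1, y = .data$trait2,
                                   fill = .data$rg)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rg)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rg") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of MR results
#'
#' @param results A tidy results tibble (`exposure, outcome, method, b,
#'   lo_ci, up_ci`), e.g. `mr_results` from [run_full_study()].
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results) {
  df <- filter(results, !is.na(.data$b)) |>
    mutate(pair = paste(.data$exposure, "→", .data$outcome))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$pair,
                                   colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo_ci,
                                          xmax = .data$up_ci),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.3) +
    ggplot2::labs(x = "Causal estimate (SD units; log OR for binary outcomes)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
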