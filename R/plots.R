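# ggplot2 views of the main result types.

SUBSTITUTION_COLORS <- c(
  "C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
  "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4"
)

category_substitution <- function(categories) {
  substr(as.character(categories), 3, 5)
}

#' Plot a 96-context mutation spectrum
#'
#' The conventional 96-bar spectrum, colored by substitution type.
#'
#' @param spectrum A spectrum from [build_spectrum()] (or any data frame with
#'   `category` and `count`).
#' @param title Plot title (defaults to the spectrum label).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, title = NULL) {
  if (is.null(title)) title <- attr(spectrum, "label") %||% "mutation spectrum"
  df <- dplyr::mutate(tibble::as_tibble(spectrum),
                      category = factor(.data$category, levels = sbs_categories()),
                      substitution = category_substitution(.data$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$substitution)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = SUBSTITUTION_COLORS, guide = "none") +
    ggplot2::facet_grid(~substitution, scales = "free_x") +
    ggplot2::labs(title = title, x = NULL, y = "count") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot extracted signatures
#'
#' One 96-bar panel per signature (probability scale).
#'
#' @param object A `signature_set` from [nmf_extract()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_set <- function(object, ...) {
  df <- tidy.signature_set(object)
  df$substitution <- category_substitution(df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$probability,
                                   fill = .data$substitution)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = SUBSTITUTION_COLORS, guide = "none") +
    ggplot2::facet_grid(signature ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Stacked signature-contribution barplot
#'
#' @param fractions Output of [contribution_fractions()].
#' @return A ggplot object.
#' @export
plot_contribution_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contribution fraction") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Excess-mutation vs covariate scatter with the fitted line
#'
#' @param points Per-sample excess points (from a pipeline result's `points`
#'   element, or any tibble with the covariate and `excess_per_mb`).
#' @param fit A `mut_regression` row for the same covariate/response.
#' @param x Covariate column (tidy-eval; default `mls_years`).
#' @return A ggplot object.
#' @export
plot_regression <- function(points, fit, x = mls_years) {
  xq <- rlang::enquo(x)
  ggplot2::ggplot(points, ggplot2::aes(x = !!xq, y = .data$excess_per_mb)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$species), size = 2) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = 2) +
    ggplot2::labs(
      y = "excess SNV frequency (per Mb)",
      subtitle = sprintf("slope %.4g, R² = %.4f, p = %.3g",
                         fit$slope, fit$r_squared, fit$p_value)) +
    ggplot2::theme_minimal(base_size = 10)
}

write_figures <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  full <- result$regressions[result$regressions$covariate == "mls" &
                               result$regressions$excluded == "", ]
  ggplot2::ggsave(file.path(dir, "excess_vs_mls.pdf"),
                  plot_regression(result$points, full), width = 6, height = 4)
  ggplot2::ggsave(file.path(dir, "signatures.pdf"),
                  autoplot.signature_set(result$signatures), width = 8, height = 5)
  ggplot2::ggsave(file.path(dir, "contribution_fractions.pdf"),
                  plot_contribution_fractions(result$fractions),
                  width = 7, height = 4)
  invisible(dir)
}
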