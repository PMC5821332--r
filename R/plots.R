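#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank-ordered bar chart of composite scores
#'
#' The classic presentation of the instrument: jurisdictions ordered by
#' composite total, bars shaded by quartile category (deeper shades mean
#' higher integration).
#'
#' @param object A `miss_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.miss_scores <- function(object, ...) {
  scores <- tibble::as_tibble(object)
  if (!"rank" %in% names(scores)) scores <- rank_jurisdictions(scores)
  if (!"quartile" %in% names(scores)) scores <- assign_quartiles(scores)
  scores$jurisdiction <- factor(scores$jurisdiction,
                                levels = rev(scores$jurisdiction))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$jurisdiction, y = .data$total,
                               fill = .data$quartile)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(very_low = "#dadaeb", low = "#9e9ac8",
                 moderate = "#6a51a3", high = "#3f007d"),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = "MISS composite score",
                  fill = "Integration quartile") +
    ggplot2::theme_minimal()
}

#' Correlation-table heatmap
#'
#' Exposure-by-outcome tile plot of Spearman coefficients with two-tailed
#' significance stars (* p < 0.05, ** p < 0.01).
#'
#' @param object A `miss_correlations` tibble from [correlation_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.miss_correlations <- function(object, ...) {
  ct <- tibble::as_tibble(object)
  stars <- c(ns = "", `p<0.05` = "*", `p<0.01` = "**")
  ct$label <- sprintf("%.2f%s", ct$rho, stars[ct$sig_flag])
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$exposure, y = .data$outcome,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Residual diagnostics panel for a block-entry fit
#'
#' Standardized residuals against standardized predicted values, the
#' linearity/homoscedasticity view reported for each regression model.
#'
#' @param object A `miss_hfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.miss_hfit <- function(object, ...) {
  fz <- object$fitted
  df <- tibble::tibble(
    std_fitted = if (stats::sd(fz) > 0) (fz - mean(fz)) / stats::sd(fz) else fz,
    std_residual = object$std_residuals
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$std_fitted,
                                   y = .data$std_residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("%s: standardized residuals vs predicted",
                                  object$outcome),
                  x = "Standardized predicted value",
                  y = "Standardized residual") +
    ggplot2::theme_minimal()
}
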