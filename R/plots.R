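#' Plot per-cell values on the tissue
#'
#' Scatter plot of the cell coordinates coloured by a gene's expression, a
#' pattern profile, or any per-cell vector.
#'
#' @param coords Cells x 2 coordinate matrix.
#' @param values Per-cell numeric vector.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_spatial <- function(coords, values, title = NULL) {
  df <- tibble::tibble(x = coords[, 1], y = coords[, 2], value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, colour = "expr") +
    ggplot2::theme_minimal()
}

#' Plot per-gene cross-validation metrics
#'
#' Histograms of the per-gene PCC, SCC and RMSE.
#'
#' @param object An `st_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("gene_id", "pcc", "scc", "rmse")],
    cols = c("pcc", "scc", "rmse"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}

#' Plot sub-reference weights against predictive power
#'
#' @param object An `st_imputation` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_imputation <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(x = .data$s, y = .data$omega,
                               colour = .data$origin)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "predictive power s", y = "ensemble weight omega") +
    ggplot2::theme_minimal()
}

#' Plot pattern profiles on the tissue
#'
#' One spatial panel per pattern profile.
#'
#' @param patterns An `st_patterns` object.
#' @param coords Cells x 2 coordinate matrix.
#' @return A ggplot object.
#' @export
plot_patterns <- function(patterns, coords) {
  prof <- patterns$profiles
  df <- dplyr::bind_rows(lapply(colnames(prof), function(p) {
    tibble::tibble(x = coords[, 1], y = coords[, 2],
                   value = prof[, p], pattern = p)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
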