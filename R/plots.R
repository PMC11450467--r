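#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display an element map
#'
#' Raster display with percentile-clipped contrast, the standard
#' presentation of quantitative XRF maps.
#'
#' @param object An `element_map`.
#' @param clip_percentile Display clip percentile (98 by convention; 99.9
#'   for cluster emphasis).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.element_map <- function(object, clip_percentile = 98, ...) {
  img <- percentile_clip(object, clip_percentile)
  um <- object$step_nm / 1000
  df <- tibble::tibble(
    x = rep(seq_len(ncol(img)), each = nrow(img)) * um,
    y = rep(rev(seq_len(nrow(img))), times = ncol(img)) * um,
    value = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey40",
                                  name = sprintf("%s\n(rel.)", object$element)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%s, clipped at the %.3g percentile",
                                  object$element, clip_percentile)) +
    ggplot2::theme_minimal()
}

#' Violin plot of cluster-size distributions
#'
#' Per-element violins with the 25th/50th/75th percentile lines drawn, the
#' conventional display of cluster-size spread.
#'
#' @param sizes Data frame with columns `element` and `size`.
#' @param size_label Axis label (default area in um^2).
#' @return A ggplot.
#' @export
plot_size_violin <- function(sizes, size_label = "cluster area (µm²)") {
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$element, y = .data$size,
                                      fill = .data$element)) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75),
                         linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = size_label) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.element_map
#' @export
autoplot.recon_slice <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    x = rep(seq_len(ncol(v)), each = nrow(v)),
    y = rep(rev(seq_len(nrow(v))), times = ncol(v)),
    value = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "recon") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
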