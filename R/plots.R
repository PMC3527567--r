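#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

grid_to_df <- function(grid, cell_km) {
  ctr <- cell_centers(nrow(grid), ncol(grid), cell_km)
  tibble::tibble(
    x = rep(ctr$x, each = nrow(grid)),
    y = rep(ctr$y, ncol(grid)),
    value = as.vector(grid)
  )
}

#' Plot a suitability map
#'
#' @param object an `nc_suitability` from [project()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nc_suitability <- function(object, ...) {
  df <- grid_to_df(object$logistic, object$cell_km)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "suitability") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east", y = "km north",
                  title = paste("Suitability,", object$period)) +
    ggplot2::theme_minimal()
}

#' Plot a binary range
#'
#' @param object an [binary_range()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nc_binary_range <- function(object, ...) {
  df <- grid_to_df(object$cells + 0, object$cell_km)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value > 0)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "darkgreen"),
                               name = "suitable") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east", y = "km north") +
    ggplot2::theme_minimal()
}

#' Plot a stacked species-richness grid
#'
#' @param richness integer matrix from [stack_richness()].
#' @param cell_km cell edge in kilometres.
#' @param title plot title.
#' @return A ggplot.
#' @export
plot_richness <- function(richness, cell_km, title = "Species richness") {
  df <- grid_to_df(richness, cell_km)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "species") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east", y = "km north", title = title) +
    ggplot2::theme_minimal()
}

#' Plot a net suitability-change grid
#'
#' Diverging scale centered on zero: negative values are deteriorating
#' cells, positive values ameliorating ones.
#'
#' @param change numeric matrix from [net_suitability_change()].
#' @param cell_km cell edge in kilometres.
#' @return A ggplot.
#' @export
plot_net_change <- function(change, cell_km) {
  df <- grid_to_df(change, cell_km)
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-lim, lim),
                                  name = "net change") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east", y = "km north",
                  title = "Net suitability change") +
    ggplot2::theme_minimal()
}
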