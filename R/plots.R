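#' Heatmap of a cluster-by-marker profile matrix
#'
#' @param profile Matrix from [cluster_profile()] (cluster x marker
#'   z-scores).
#' @return A ggplot.
#' @export
plot_cluster_heatmap <- function(profile) {
  df <- as_tibble(profile, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "marker", values_to = "z")
  df$marker <- factor(df$marker, levels = colnames(profile))
  df$cluster <- factor(df$cluster, levels = rev(rownames(profile)))
  ggplot2::ggplot(df, ggplot2::aes(.data$marker, .data$cluster,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of cell positions in an ROI
#'
#' @param cells Cell table (one ROI, or faceted by `roi_id`).
#' @param color Column mapped to color (default `population` if present,
#'   else `cluster`).
#' @return A ggplot with reversed y (image convention).
#' @export
plot_roi_cells <- function(cells, color = NULL) {
  color <- color %||%
    (if ("population" %in% names(cells)) "population" else "cluster")
  ggplot2::ggplot(cells, ggplot2::aes(.data$centroid_x, .data$centroid_y,
                                      color = .data[[color]])) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~roi_id) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @describeIn build_tumor_mask Raster plot of the tumor mask or its
#'   distance map.
#' @param object A `tumor_mask`.
#' @param what `"mask"` or `"distance"`.
#' @param ... Unused.
#' @export
autoplot.tumor_mask <- function(object, what = c("mask", "distance"), ...) {
  what <- match.arg(what)
  m <- if (what == "mask") object$mask * 1 else object$distance_map
  df <- tibble(
    x = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = if (what == "mask") "tumor" else "distance (px)") +
    ggplot2::theme_void()
}
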