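#' Nearest-member distance from a reference to a target cluster
#'
#' For every reference-cluster cell, the Euclidean centroid distance (px) to
#' the nearest target-cluster cell in the same ROI. Reference cells in ROIs
#' where the target cluster is absent get `NA` and are excluded from pooled
#' summaries. A cell belonging to both clusters never counts as its own
#' neighbor.
#'
#' @param cells Cell table with `roi_id`, `centroid_x`, `centroid_y` and a
#'   cluster label column.
#' @param ref_cluster,target_cluster Cluster labels.
#' @param tissue Optional `tissue_type` filter applied before the analysis.
#' @param cluster_col Label column name.
#' @return Tibble with one row per reference cell: `roi_id`, `cell_id`,
#'   `target_cluster`, `nearest_distance_px`.
#' @export
nn_distance_to_cluster <- function(cells, ref_cluster, target_cluster,
                                   tissue = NULL, cluster_col = "cluster") {
  dat <- filter_tissue(cells, tissue)
  ref <- dat[dat[[cluster_col]] == ref_cluster, , drop = FALSE]
  if (nrow(ref) == 0L) {
    warn("no reference cells after filtering; empty result")
    return(tibble(roi_id = character(), cell_id = integer(),
                  target_cluster = character(),
                  nearest_distance_px = double()))
  }
  tar <- dat[dat[[cluster_col]] == target_cluster, , drop = FALSE]
  res <- lapply(split(seq_len(nrow(ref)), ref$roi_id), function(ri) {
    r <- ref[ri, , drop = FALSE]
    t_roi <- tar[tar$roi_id == r$roi_id[1], , drop = FALSE]
    d <- nearest_dist(r, t_roi)
    tibble(roi_id = r$roi_id, cell_id = r$cell_id,
           target_cluster = target_cluster, nearest_distance_px = d)
  })
  dplyr::bind_rows(res)
}

filter_tissue <- function(cells, tissue) {
  if (is.null(tissue)) return(cells)
  cells[cells$tissue_type %in% tissue, , drop = FALSE]
}

# distance from each row of ref to nearest row of tar (same ROI), excluding
# self-pairs identified by cell_id
nearest_dist <- function(ref, tar) {
  if (nrow(tar) == 0L) return(rep(NA_real_, nrow(ref)))
  d2 <- outer(ref$centroid_x, tar$centroid_x, "-")^2 +
    outer(ref$centroid_y, tar$centroid_y, "-")^2
  self <- outer(ref$cell_id, tar$cell_id, "==")
  d2[self] <- Inf
  d <- sqrt(apply(d2, 1, min))
  d[!is.finite(d)] <- NA_real_
  d
}

#' Count target-cluster cells within a radius of each reference cell
#'
#' Counts target cells at centroid distance `<= radius_um / pixel_size_um`
#' (boundary inclusive) within the same ROI; self-pairs excluded. The
#' ROI-level aggregate is the mean count over reference cells.
#'
#' @inheritParams nn_distance_to_cluster
#' @param radius_um Neighborhood radius in microns.
#' @param pixel_size_um Microns per pixel (Hyperion: 1, so 20 um = 20 px).
#' @return Tibble with one row per reference cell: `roi_id`, `cell_id`,
#'   `target_cluster`, `n_within_radius`.
#' @export
neighbors_within <- function(cells, ref_cluster, target_cluster,
                             radius_um = 20, pixel_size_um = 1,
                             tissue = NULL, cluster_col = "cluster") {
  dat <- filter_tissue(cells, tissue)
  ref <- dat[dat[[cluster_col]] == ref_cluster, , drop = FALSE]
  if (nrow(ref) == 0L) {
    warn("no reference cells after filtering; empty result")
    return(tibble(roi_id = character(), cell_id = integer(),
                  target_cluster = character(), n_within_radius = integer()))
  }
  tar <- dat[dat[[cluster_col]] == target_cluster, , drop = FALSE]
  r_px <- radius_um / pixel_size_um
  res <- lapply(split(seq_len(nrow(ref)), ref$roi_id), function(ri) {
    r <- ref[ri, , drop = FALSE]
    t_roi <- tar[tar$roi_id == r$roi_id[1], , drop = FALSE]
    if (nrow(t_roi) == 0L) {
      n <- rep(0L, nrow(r))
    } else {
      d2 <- outer(r$centroid_x, t_roi$centroid_x, "-")^2 +
        outer(r$centroid_y, t_roi$centroid_y, "-")^2
      self <- outer(r$cell_id, t_roi$cell_id, "==")
      d2[self] <- Inf
      n <- as.integer(rowSums(d2 <= r_px^2))
    }
    tibble(roi_id = r$roi_id, cell_id = r$cell_id,
           target_cluster = target_cluster, n_within_radius = n)
  })
  dplyr::bind_rows(res)
}

#' Compare neighborhoods of a reference cluster across target clusters
#'
#' For each target cluster: the pooled median nearest-member distance over
#' all reference cells (cells in ROIs lacking the target excluded), the mean
#' within-radius count per ROI, and pairwise Wilcoxon rank-sum tests (BH
#' adjusted) on the per-cell distance sets. Targets never co-occurring with
#' the reference on any ROI are dropped from the table.
#'
#' @inheritParams neighbors_within
#' @param target_clusters Labels to compare; default: every other cluster.
#' @return An object of class `neighborhood_comparison`: list with
#'   `summary` (one row per target, ranked by pooled median distance),
#'   `per_cell` (distances and counts per reference cell), `per_roi`
#'   (mean counts), and `tests` (pairwise BH-adjusted rank-sum results).
#' @export
compare_neighborhoods <- function(cells, ref_cluster, target_clusters = NULL,
                                  radius_um = 20, pixel_size_um = 1,
                                  tissue = NULL, cluster_col = "cluster") {
  dat <- filter_tissue(cells, tissue)
  target_clusters <- target_clusters %||%
    setdiff(unique(dat[[cluster_col]]), ref_cluster)
  per_cell <- purrr::map_dfr(target_clusters, function(tc) {
    d <- nn_distance_to_cluster(dat, ref_cluster, tc, cluster_col = cluster_col)
    n <- neighbors_within(dat, ref_cluster, tc, radius_um = radius_um,
                          pixel_size_um = pixel_size_um,
                          cluster_col = cluster_col)
    dplyr::left_join(d, n, by = c("roi_id", "cell_id", "target_cluster"))
  })
  summary <- per_cell |>
    dplyr::group_by(.data$target_cluster) |>
    dplyr::summarise(
      n_ref_cells = dplyr::n(),
      n_with_target = sum(!is.na(.data$nearest_distance_px)),
      median_distance_px = median(.data$nearest_distance_px, na.rm = TRUE),
      mean_n_within_radius = mean(.data$n_within_radius),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_with_target > 0L) |>
    dplyr::arrange(.data$median_distance_px)
  per_roi <- per_cell |>
    dplyr::group_by(.data$target_cluster, .data$roi_id) |>
    dplyr::summarise(mean_n_within_radius = mean(.data$n_within_radius),
                     .groups = "drop")
  tests <- pairwise_distance_tests(per_cell, summary$target_cluster)
  structure(list(ref_cluster = ref_cluster, radius_um = radius_um,
                 summary = summary, per_cell = per_cell, per_roi = per_roi,
                 tests = tests),
            class = "neighborhood_comparison")
}

pairwise_distance_tests <- function(per_cell, targets) {
  if (length(targets) < 2L)
    return(tibble(cluster_a = character(), cluster_b = character(),
                  statistic = double(), p_value = double(),
                  p_adj = double()))
  pairs <- utils::combn(targets, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- per_cell$nearest_distance_px[
      per_cell$target_cluster == pairs[1, i] &
        !is.na(per_cell$nearest_distance_px)]
    b <- per_cell$nearest_distance_px[
      per_cell$target_cluster == pairs[2, i] &
        !is.na(per_cell$nearest_distance_px)]
    tt <- run_test(a, b, test = "wilcoxon_rank_sum")
    tibble(cluster_a = pairs[1, i], cluster_b = pairs[2, i],
           statistic = tt$statistic, p_value = tt$p_value)
  })
  res$p_adj <- bh_adjust(res$p_value)
  res
}

#' @export
print.neighborhood_comparison <- function(x, ...) {
  cat(sprintf("<neighborhood_comparison> reference '%s', radius %g um\n",
              x$ref_cluster, x$radius_um))
  print(x$summary)
  invisible(x)
}

#' @rdname compare_neighborhoods
#' @param object,x A `neighborhood_comparison`.
#' @param ... Unused.
#' @export
tidy.neighborhood_comparison <- function(x, ...) x$summary

#' @rdname compare_neighborhoods
#' @export
autoplot.neighborhood_comparison <- function(object, ...) {
  dat <- dplyr::filter(object$per_cell, !is.na(.data$nearest_distance_px))
  ord <- object$summary$target_cluster
  dat$target_cluster <- factor(dat$target_cluster, levels = ord)
  ggplot2::ggplot(dat, ggplot2::aes(.data$target_cluster,
                                    .data$nearest_distance_px)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "nearest-member distance (px)",
                  title = paste0("distances from ", object$ref_cluster)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
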