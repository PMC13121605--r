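#' Dataset-wide z-scoring of marker signals
#'
#' Centers and scales each marker column over the whole table (population
#' standard deviation, i.e. the n denominator), the scaling used before
#' graph clustering. Constant columns map to all zeros with a warning.
#'
#' @param cells Cell table.
#' @param markers Marker names; defaults to all transformed markers.
#' @param prefix Column prefix to read (`"tfm"` by default).
#' @return Numeric cells x markers matrix with per-column mean 0, sd 1.
#' @export
zscore_markers <- function(cells, markers = NULL, prefix = "tfm") {
  markers <- markers %||% cell_markers(cells, prefix)
  m <- marker_matrix(cells, markers, prefix)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  flat <- sdev == 0
  if (any(flat)) {
    warn(paste0("constant marker column(s) mapped to zero: ",
                paste(markers[flat], collapse = ", ")))
    sdev[flat] <- 1
  }
  z <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdev
  z
}

# Shared-nearest-neighbor graph: kNN by Euclidean distance (ties broken by
# row index), edges weighted by the Jaccard overlap of neighbor sets.
snn_graph <- function(z, k) {
  n <- nrow(z)
  if (n <= k) {
    warn(sprintf("n = %d <= k = %d; reducing k to %d", n, k, n - 1L))
    k <- n - 1L
  }
  nn <- knn_index_cpp(z, as.integer(k))
  # neighbor sets include the point itself for the Jaccard overlap
  sets <- cbind(seq_len(n), nn)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  member <- Matrix::sparseMatrix(
    i = rep(seq_len(n), times = k + 1L), j = as.vector(sets),
    x = 1, dims = c(n, n)
  )
  inter <- Matrix::rowSums(member[edges[, 1], , drop = FALSE] *
                             member[edges[, 2], , drop = FALSE])
  jac <- inter / (2 * (k + 1L) - inter)
  keep <- jac > 0
  igraph::graph_from_data_frame(
    data.frame(from = edges[keep, 1], to = edges[keep, 2],
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

#' Leiden community detection on a shared-nearest-neighbor graph
#'
#' The clustering engine shared by the IMC and RNA stages: a kNN graph
#' (Euclidean metric) is weighted by Jaccard overlap of neighbor sets and
#' partitioned by Leiden modularity optimization at the given resolution.
#' Deterministic for a fixed seed.
#'
#' @param z Numeric observation x feature matrix (typically z-scored markers
#'   or principal components).
#' @param k Number of nearest neighbors (default 30, the PhenoGraph
#'   convention). Reduced with a warning when `n <= k`.
#' @param resolution Positive Leiden resolution; larger values give more,
#'   smaller clusters.
#' @param seed Integer seed.
#' @return Integer cluster labels (1-based), one per row of `z`.
#' @export
leiden_knn <- function(z, k = 30, resolution = 1, seed = 42) {
  stopifnot(resolution > 0)
  n <- nrow(z)
  if (n < 2L) return(rep(1L, n))
  if (nrow(unique(z)) == 1L) return(rep(1L, n))
  g <- snn_graph(z, k)
  memb <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 3
    ))
  })
  as.integer(memb)
}

#' Cluster gated cells on z-scored marker signals
#'
#' Runs [zscore_markers()] then [leiden_knn()] and writes the labels into the
#' table as text (`"C01"`, `"C02"`, ...). Clustering metadata (markers,
#' scaling, k, resolution, seed, sizes) is attached as the
#' `"cluster_model"` attribute.
#'
#' @inheritParams zscore_markers
#' @inheritParams leiden_knn
#' @param cluster_col Name of the label column to create.
#' @return `cells` with a cluster label column.
#' @export
cluster_cells <- function(cells, markers = NULL, k = 30, resolution = 1,
                          seed = 42, prefix = "tfm", cluster_col = "cluster") {
  z <- zscore_markers(cells, markers, prefix)
  labels <- leiden_knn(z, k = k, resolution = resolution, seed = seed)
  cells[[cluster_col]] <- sprintf("C%02d", labels)
  attr(cells, "cluster_model") <- list(
    markers = colnames(z), center = attr(z, "center"),
    scale = attr(z, "scale"), k = k, resolution = resolution, seed = seed,
    sizes = table(cells[[cluster_col]])
  )
  cells
}

#' Cluster-by-marker profile matrix for heatmaps
#'
#' Mean transformed marker signal per cluster, then marker-wise z-scoring
#' across clusters (population sd). With a single cluster the z-scores are
#' defined as zero.
#'
#' @param cells Cell table with a cluster label column.
#' @param markers Markers to profile; default all transformed markers.
#' @param cluster_col Label column name.
#' @param prefix Marker column prefix.
#' @return Numeric cluster x marker matrix of z-scores.
#' @export
cluster_profile <- function(cells, markers = NULL, cluster_col = "cluster",
                            prefix = "tfm") {
  markers <- markers %||% cell_markers(cells, prefix)
  m <- marker_matrix(cells, markers, prefix)
  lab <- as.character(cells[[cluster_col]])
  means <- rowsum(m, lab) / as.vector(table(lab)[sort(unique(lab))])
  if (nrow(means) < 2L) return(means * 0)
  mu <- colMeans(means)
  sdev <- sqrt(colMeans(sweep(means, 2, mu)^2))
  sdev[sdev == 0] <- 1
  sweep(sweep(means, 2, mu), 2, sdev, "/")
}

#' Split one cluster by a gate
#'
#' Re-gates the members of a single cluster (the manual "split" operation
#' used when one cluster mixes two lineages, e.g. a CD4/CD8 double-positive
#' cluster): members satisfying the gate get `new_names[2]`, the rest
#' `new_names[1]`. All other labels are untouched.
#'
#' @param cells Cell table with a cluster label column.
#' @param cluster_id Label of the cluster to split.
#' @param gate A `gate_spec` evaluated on the cluster's members.
#' @param new_names Character vector of length 2: name for members failing
#'   the gate, then for members passing it.
#' @param cluster_col Label column name.
#' @param prefix Marker column prefix used by the gate.
#' @return `cells` with updated labels.
#' @export
split_cluster <- function(cells, cluster_id, gate,
                          new_names = paste0(cluster_id, c("_rest", "_split")),
                          cluster_col = "cluster", prefix = "tfm") {
  stopifnot(length(new_names) == 2L)
  lab <- as.character(cells[[cluster_col]])
  in_target <- lab == cluster_id
  if (!any(in_target)) abort(paste0("no cells in cluster '", cluster_id, "'"))
  hit <- apply_gate(cells[in_target, , drop = FALSE], gate, prefix = prefix)
  lab[in_target] <- ifelse(hit, new_names[2], new_names[1])
  cells[[cluster_col]] <- lab
  cells
}

#' 2-D UMAP embedding for visualization
#'
#' Deterministic for a fixed seed (single-threaded SGD). The embedding is for
#' display only; no statistic in the pipeline reads it.
#'
#' @param z Numeric observation x feature matrix.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (capped at n - 1).
#' @return Tibble with columns `u`, `v`.
#' @export
embed_2d <- function(z, seed = 42, n_neighbors = 15) {
  n <- nrow(z)
  nb <- max(2L, min(n_neighbors, n - 1L))
  init <- if (nrow(z) < 20) "random" else "spectral"
  coords <- withr::with_seed(seed, {
    uwot::umap(z, n_neighbors = nb, n_threads = 1, n_sgd_threads = 0,
               init = init, verbose = FALSE)
  })
  tibble(u = coords[, 1], v = coords[, 2])
}
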