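# Independent brute-force oracles. These re-derive each quantity from its
# definition by direct enumeration and are deliberately slow and simple.

brute_edt_sq <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (nrow(fg) == 0) return(out)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- min((fg[, 1] - i)^2 + (fg[, 2] - j)^2)
  }
  out
}

# 0-based Otsu bin by direct evaluation of the between-class variance
brute_otsu_bin <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(0L)
  b <- pmin(floor((v - lo) / ((hi - lo) / n_bins)), n_bins - 1L)
  best <- -Inf; best_t <- 0L
  mids <- (seq_len(n_bins) - 0.5)
  for (t in 0:(n_bins - 2L)) {
    g0 <- b <= t; g1 <- !g0
    w0 <- mean(g0); w1 <- mean(g1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(mids[b[g0] + 1L]); mu1 <- mean(mids[b[g1] + 1L])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# literal per-pixel ImageJ count-rule morphology
brute_morph <- function(mask, op, iterations, count) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  nb <- function(mm, i, j, fg) {
    tot <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      val <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) FALSE else mm[ii, jj]
      if (val == fg) tot <- tot + 1L
    }
    tot
  }
  for (it in seq_len(iterations)) {
    out <- m
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (op == "erode" && m[i, j] && nb(m, i, j, FALSE) >= count)
        out[i, j] <- FALSE
      if (op == "dilate" && !m[i, j] && nb(m, i, j, TRUE) >= count)
        out[i, j] <- TRUE
    }
    m <- out
  }
  m
}

# 8-connected component sizes by queue flood fill
brute_components <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!m[i0, j0] || lab[i0, j0]) next
    cur <- cur + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

brute_remove_small <- function(mask, min_px) {
  lab <- brute_components(mask)
  if (max(lab) == 0L) return(mask > 0)
  sizes <- tabulate(lab[lab > 0L])
  out <- mask > 0
  for (k in seq_along(sizes)) if (sizes[k] < min_px) out[lab == k] <- FALSE
  out
}

# all-pairs within-radius counts per reference cell, same-ROI, self excluded
brute_neighbors_within <- function(cells, ref_cluster, target_cluster,
                                   radius_px) {
  ref <- cells[cells$cluster == ref_cluster, ]
  tar <- cells[cells$cluster == target_cluster, ]
  vapply(seq_len(nrow(ref)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(tar))) {
      if (ref$roi_id[i] != tar$roi_id[j]) next
      if (ref$cell_id[i] == tar$cell_id[j]) next
      d <- sqrt((ref$centroid_x[i] - tar$centroid_x[j])^2 +
                  (ref$centroid_y[i] - tar$centroid_y[j])^2)
      if (d <= radius_px) n <- n + 1L
    }
    n
  }, 0L)
}

# NNLS oracle: exhaustive grid search over non-negative t for 2 channels
grid_nnls2 <- function(s, raw, t_max = 2, step = 0.002) {
  grid <- seq(0, t_max, by = step)
  best <- c(NA, NA); best_r <- Inf
  for (t1 in grid) for (t2 in grid) {
    r <- sum((c(t1, t2) %*% s - raw)^2)
    if (r < best_r) { best_r <- r; best <- c(t1, t2) }
  }
  list(x = best, resid = best_r)
}

# small in-memory ROI builders
toy_roi <- function(channel_list, roi_id = "toy") {
  roi_image(channel_list, channels = names(channel_list), roi_id = roi_id)
}

toy_cells <- function(x, y, cluster, roi_id = "ROI001", cell_id = NULL) {
  tibble::tibble(
    cell_id = cell_id %||% seq_along(x), roi_id = roi_id,
    patient_id = "P01", tissue_type = "adjacent",
    centroid_x = x, centroid_y = y, cluster = cluster
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_mask <- function(nr, nc, p = 0.3) matrix(runif(nr * nc) < p, nr, nc)

skip_if_no_mclust <- function() {
  testthat::skip_if_not_installed("mclust")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

small_scenario <- function(seed = 7, roi_px = 300) {
  sc <- default_scenario(seed = seed, roi_px = roi_px)
  # scale abundances to the smaller field of view, same composition
  f <- (roi_px / 1000)^2
  sc$populations$abundance <- sc$populations$abundance * f
  sc
}
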