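#' Otsu threshold on a 256-bin histogram
#'
#' Values are min-max scaled into 256 bins (the behavior of 8-bit conversion
#' in ImageJ before automatic thresholding); the returned cut maximizes the
#' between-class variance, with ties broken by the lowest qualifying
#' threshold. A pixel is foreground when its value is `>=` the returned cut.
#'
#' @param values Numeric vector or matrix of intensities.
#' @param n_bins Number of histogram bins.
#' @return Threshold on the original value scale (scalar). The selected bin
#'   index (0-based; foreground = bins strictly above it) is attached as
#'   attribute `"bin"`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warn("constant input to otsu_threshold; returning lowest bin")
    return(structure(lo, bin = 0L))
  }
  bw <- (hi - lo) / n_bins
  b <- pmin(floor((v - lo) / bw), n_bins - 1L)  # 0-based bin index
  counts <- tabulate(b + 1L, nbins = n_bins)
  p <- counts / length(v)
  mids <- (seq_len(n_bins) - 0.5)
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  # candidate t: class 0 = bins 0..t, evaluated for t = 0..n_bins-2
  t_idx <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[t_idx]
  valid <- w0[t_idx] > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0[t_idx][valid] - m0[t_idx][valid])^2 /
    (w0[t_idx][valid] * w1[valid])
  t_best <- which.max(bcv) - 1L  # lowest maximizer (which.max takes first)
  structure(lo + (t_best + 1L) * bw, bin = t_best)
}

#' Gaussian blur with reflective boundaries
#'
#' Separable isotropic Gaussian convolution, kernel truncated at
#' `ceiling(4 * sigma)` and renormalized, edges handled by reflection, so a
#' constant image is unchanged and total intensity of interior-supported
#' blobs is preserved.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(image, sigma = 0.8) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    nr <- nrow(m); nc <- ncol(m)
    if (along_rows) {
      # reflect rows: index i + off with mirror boundary
      out <- matrix(0, nr, nc)
      for (off in -r:r) {
        idx <- seq_len(nr) + off
        idx <- ifelse(idx < 1L, 2L - idx, idx)
        idx <- ifelse(idx > nr, 2L * nr - idx, idx)
        out <- out + k[off + r + 1L] * m[idx, , drop = FALSE]
      }
      out
    } else {
      out <- matrix(0, nr, nc)
      for (off in -r:r) {
        idx <- seq_len(nc) + off
        idx <- ifelse(idx < 1L, 2L - idx, idx)
        idx <- ifelse(idx > nc, 2L * nc - idx, idx)
        out <- out + k[off + r + 1L] * m[, idx, drop = FALSE]
      }
      out
    }
  }
  conv1(conv1(image, TRUE), FALSE)
}

# count of foreground 8-neighbors for every pixel; outside the image is
# treated as background
neighbor_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    cnt <- cnt + pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  cnt
}

#' Count-based binary morphology (ImageJ semantics)
#'
#' ImageJ's binary erode/dilate with a neighbor *count*: one erosion
#' iteration removes a foreground pixel iff at least `count` of its 8
#' neighbors are background; one dilation iteration adds a background pixel
#' iff at least `count` of its 8 neighbors are foreground. Pixels outside the
#' image count as background. This differs from structuring-element
#' morphology and is implemented to match the macro semantics exactly.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param op `"erode"` or `"dilate"`.
#' @param iterations Number of repeated passes.
#' @param count Neighbor count threshold in 1..8.
#' @return Logical matrix.
#' @export
binary_morph <- function(mask, op = c("erode", "dilate"), iterations = 1L,
                         count = 1L) {
  op <- match.arg(op)
  stopifnot(count >= 1L, count <= 8L, iterations >= 0L)
  m <- mask > 0
  for (i in seq_len(iterations)) {
    if (op == "erode") {
      bg_nb <- 8L - neighbor_count8(m)   # background neighbors (incl. border)
      m <- m & !(bg_nb >= count)
    } else {
      fg_nb <- neighbor_count8(m)
      m <- m | (fg_nb >= count)
    }
  }
  m
}

#' Morphological opening with count semantics
#'
#' `iterations` erosions followed by `iterations` dilations, each with the
#' given neighbor count.
#'
#' @inheritParams binary_morph
#' @return Logical matrix.
#' @export
binary_open <- function(mask, iterations = 1L, count = 1L) {
  binary_morph(binary_morph(mask, "erode", iterations, count),
               "dilate", iterations, count)
}

#' Label 8-connected foreground components
#'
#' @param mask Logical matrix.
#' @return Integer matrix; components numbered from 1 in scan order,
#'   0 = background.
#' @export
label_components <- function(mask) {
  label_cc8_cpp(mask > 0)
}

#' Remove small connected components
#'
#' Deletes 8-connected foreground components with fewer than `min_px` pixels;
#' components of exactly `min_px` pixels are kept.
#'
#' @param mask Logical matrix.
#' @param min_px Minimum component size (pixels) to keep.
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_px = 200L) {
  m <- mask > 0
  lab <- label_cc8_cpp(m)
  if (max(lab) == 0L) return(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_px
  m & keep[pmax(lab, 1L)]
}

#' Exact Euclidean distance transform
#'
#' Distance from every background pixel to the nearest foreground (`TRUE`)
#' pixel, 0 on foreground pixels, computed with the exact two-pass
#' lower-envelope algorithm (squared distances are exact integers).
#'
#' @param mask Logical matrix.
#' @param squared Return squared distances (exact integers) instead of
#'   distances.
#' @return Numeric matrix. If the mask has no foreground pixel, all entries
#'   are `NaN` with a warning.
#' @export
edt <- function(mask, squared = FALSE) {
  m <- mask > 0
  if (!any(m)) {
    warn("mask has no foreground pixels; distance map undefined (NaN)")
    return(matrix(NaN, nrow(m), ncol(m)))
  }
  d2 <- edt_sq_cpp(m)
  if (squared) d2 else sqrt(d2)
}

#' Build a tumor mask from epithelial/stromal channels
#'
#' Reproduces the ImageJ macro used to delineate tumor areas: sum the CK18
#' and alpha-SMA channels, Gaussian-filter (sigma 0.8), threshold with Otsu,
#' smoothen with open (5 iterations, count 1), remove objects smaller than
#' 200 px, dilate (9 iterations, count 1). Instead of storing the inverted
#' mask plus its distance map separately, the result carries the binary
#' tumor mask and the Euclidean distance-to-tumor map (0 inside tumor) —
#' the same information.
#'
#' @param roi An [roi_image()].
#' @param channels Channels summed to highlight tumor tissue.
#' @param sigma Gaussian blur sd (px).
#' @param open_iter,open_count Opening parameters.
#' @param min_px Minimum object size kept.
#' @param dilate_iter,dilate_count Dilation parameters.
#' @return An object of class `tumor_mask`: list with `roi_id`, `mask`
#'   (logical matrix), `distance_map` (px; `NaN` everywhere when the mask is
#'   empty), and `threshold`.
#' @export
build_tumor_mask <- function(roi, channels = c("CK18", "aSMA"), sigma = 0.8,
                             open_iter = 5L, open_count = 1L, min_px = 200L,
                             dilate_iter = 9L, dilate_count = 1L) {
  missing <- setdiff(channels, roi$channels)
  if (length(missing))
    abort(paste0("required channel(s) absent: ", paste(missing, collapse = ", ")))
  comp <- Reduce(`+`, lapply(channels, function(ch) roi_channel(roi, ch)))
  if (max(comp) == min(comp)) {
    warn("flat composite image; tumor mask is empty")
    empty <- matrix(FALSE, nrow(comp), ncol(comp))
    return(structure(list(roi_id = roi$roi_id, mask = empty,
                          distance_map = matrix(NaN, nrow(comp), ncol(comp)),
                          threshold = NA_real_),
                     class = "tumor_mask"))
  }
  blurred <- gaussian_blur(comp, sigma = sigma)
  thr <- otsu_threshold(blurred)
  inform(sprintf("otsu threshold %.4g on min-max scaled composite (bin %d/256)",
                 as.numeric(thr), attr(thr, "bin")))
  m <- blurred >= as.numeric(thr)
  m <- binary_open(m, iterations = open_iter, count = open_count)
  m <- remove_small_objects(m, min_px = min_px)
  m <- binary_morph(m, "dilate", iterations = dilate_iter, count = dilate_count)
  dm <- if (any(m)) edt(m) else matrix(NaN, nrow(m), ncol(m))
  structure(list(roi_id = roi$roi_id, mask = m, distance_map = dm,
                 threshold = as.numeric(thr)),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask '%s'> %d x %d px, tumor fraction %.1f%%\n",
              x$roi_id, nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Assign cells to tumor / stroma regions
#'
#' Maps each cell centroid (rounded half-up to the nearest pixel, clamped to
#' the image with a warning if outside) onto the tumor mask and distance
#' map. Cells outside the tumor mask of an adenocarcinoma ROI constitute the
#' stroma.
#'
#' @param cells Cell table with `centroid_x` / `centroid_y` (0-based px).
#' @param tm A [build_tumor_mask()] result for the same ROI.
#' @return `cells` with added `in_tumor` (logical), `distance_to_tumor` (px)
#'   and `region` (`"tumor"` / `"stroma"`) columns.
#' @export
assign_tissue_region <- function(cells, tm) {
  nr <- nrow(tm$mask); nc <- ncol(tm$mask)
  col1 <- floor(cells$centroid_x + 0.5) + 1L  # round-half-up, 1-based col
  row1 <- floor(cells$centroid_y + 0.5) + 1L
  out_of_bounds <- col1 < 1L | col1 > nc | row1 < 1L | row1 > nr
  if (any(out_of_bounds)) {
    warn(sprintf("%d centroid(s) outside image after rounding; clamped",
                 sum(out_of_bounds)))
    col1 <- pmin(pmax(col1, 1L), nc)
    row1 <- pmin(pmax(row1, 1L), nr)
  }
  idx <- cbind(row1, col1)
  cells$in_tumor <- tm$mask[idx]
  cells$distance_to_tumor <- tm$distance_map[idx]
  cells$region <- dplyr::if_else(cells$in_tumor, "tumor", "stroma")
  cells
}
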