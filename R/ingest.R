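#' Construct an ROI image
#'
#' Container for one imaging-mass-cytometry region of interest: a stack of
#' channel images (ion counts, arbitrary non-negative units) plus channel
#' (marker) names and the physical pixel size.
#'
#' @param pixels Numeric array `height x width x n_channels`, all values >= 0,
#'   or a list of equally sized matrices (one per channel).
#' @param channels Character vector of unique marker names, one per channel.
#' @param roi_id Identifier for the ROI.
#' @param pixel_size_um Microns per pixel (Hyperion ablation spots are 1 um).
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(pixels, channels, roi_id = "roi", pixel_size_um = 1) {
  if (is.list(pixels)) {
    dims <- unique(lapply(pixels, dim))
    if (length(dims) != 1L) abort("all channel matrices must share dimensions")
    pixels <- array(unlist(pixels, use.names = FALSE),
                    dim = c(dims[[1]], length(pixels)))
  }
  if (length(dim(pixels)) != 3L) abort("`pixels` must be a h x w x channel array")
  if (dim(pixels)[3] != length(channels))
    abort("number of channels does not match length of `channels`")
  if (anyDuplicated(channels)) abort("channel names must be unique")
  if (min(pixels) < 0) abort("intensities must be non-negative")
  storage.mode(pixels) <- "double"
  dimnames(pixels) <- list(NULL, NULL, channels)
  structure(
    list(roi_id = roi_id, channels = channels, pixels = pixels,
         pixel_size_um = pixel_size_um),
    class = "roi_image"
  )
}

#' @export
print.roi_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<roi_image '%s'> %d x %d px (%g um/px), %d channels: %s\n",
              x$roi_id, d[1], d[2], x$pixel_size_um, d[3],
              paste(utils::head(x$channels, 6), collapse = ", ")))
  invisible(x)
}

#' Extract a single channel as a matrix
#' @param roi An [roi_image()].
#' @param channel Marker name.
#' @return Numeric `height x width` matrix.
#' @export
roi_channel <- function(roi, channel) {
  if (!channel %in% roi$channels)
    abort(paste0("channel '", channel, "' not present in ROI"))
  roi$pixels[, , channel]
}

# 16-bit encoding used for all TIFF round trips: integer counts/labels are
# stored as value / 65535 and read back natively with as.is = TRUE.
.TIFF_MAX <- 65535

#' Write an ROI image and its label mask as TIFF files
#'
#' The multichannel image is written as a multi-page 16-bit TIFF (one page per
#' channel, in channel order); the mask as a single-page 16-bit TIFF. Values
#' must be integers in `[0, 65535]`, which the synthetic generator guarantees.
#'
#' @param roi An [roi_image()].
#' @param mask Integer label matrix (0 = background) with the image dimensions.
#' @param image_path,mask_path Output file paths.
#' @return Invisibly, the image path.
#' @export
write_roi <- function(roi, mask, image_path, mask_path) {
  px <- roi$pixels
  if (max(px) > .TIFF_MAX || max(mask) > .TIFF_MAX)
    abort("values above 65535 cannot be stored in 16-bit TIFF pages")
  pages <- lapply(seq_along(roi$channels), function(k) round(px[, , k]) / .TIFF_MAX)
  tiff::writeTIFF(pages, image_path, bits.per.sample = 16L)
  tiff::writeTIFF(mask / .TIFF_MAX, mask_path, bits.per.sample = 16L)
  invisible(image_path)
}

#' Read an ROI image and segmentation mask from TIFF files
#'
#' Reads a multi-page channel TIFF and a single-page integer label mask, and
#' renames channels according to the panel. Integer TIFF data are read
#' natively (ion counts), then promoted to double.
#'
#' @param image_path Multi-page TIFF, one page per panel channel, panel order.
#' @param mask_path Single-page integer TIFF, 0 = background.
#' @param panel Data frame with columns `channel` and `marker` (one row per
#'   page), or a character vector of marker names.
#' @param roi_id ROI identifier; defaults to the image file stem.
#' @param pixel_size_um Microns per pixel.
#' @return A list with elements `image` ([roi_image()]) and `mask` (integer
#'   matrix).
#' @export
read_roi <- function(image_path, mask_path, panel,
                     roi_id = NULL, pixel_size_um = 1) {
  markers <- if (is.data.frame(panel)) as.character(panel$marker) else as.character(panel)
  pages <- tiff::readTIFF(image_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(markers))
    abort(sprintf("TIFF has %d pages but panel lists %d channels",
                  length(pages), length(markers)))
  mask <- tiff::readTIFF(mask_path, as.is = TRUE)
  if (is.double(mask) && any(mask != round(mask)))
    abort("mask TIFF does not contain integer labels")
  mask <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
  if (!all(dim(pages[[1]]) == dim(mask)))
    abort(sprintf("mask is %d x %d but image pages are %d x %d",
                  nrow(mask), ncol(mask), nrow(pages[[1]]), ncol(pages[[1]])))
  roi_id <- roi_id %||% sub("\\.tiff?$", "", basename(image_path))
  img <- roi_image(lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  }), channels = markers, roi_id = roi_id, pixel_size_um = pixel_size_um)
  list(image = img, mask = mask)
}

#' Read a panel file
#'
#' @param path CSV with columns `channel`, `marker`, and optionally
#'   `use_for_clustering` (logical).
#' @return A tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("channel", "marker") %in% names(panel)))
    abort("panel must have columns 'channel' and 'marker'")
  panel
}

#' Read a spillover matrix
#'
#' @param path Square CSV; header row and first column carry channel names,
#'   rows = emitting channel, columns = receiving channel.
#' @return A named square matrix with unit diagonal.
#' @export
read_spillover <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  s <- as.matrix(df[, -1])
  rownames(s) <- df[[1]]
  validate_spillover(s)
}

validate_spillover <- function(s) {
  if (nrow(s) != ncol(s)) abort("spillover matrix must be square")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    abort("spillover matrix must carry channel names on rows and columns")
  if (!identical(rownames(s), colnames(s)))
    abort("spillover row and column names must match")
  if (any(abs(diag(s) - 1) > 1e-12)) abort("spillover diagonal must be 1")
  off <- s - diag(diag(s))
  if (any(off < 0) || any(off >= 1))
    abort("off-diagonal spillover entries must lie in [0, 1)")
  s
}

#' Build a per-cell feature table from an ROI image and label mask
#'
#' One row per distinct nonzero label. Raw marker values are the arithmetic
#' mean ion count over the label's pixels; the centroid is the unweighted mean
#' of member pixel coordinates (0-based, `x` = column index).
#'
#' @param roi An [roi_image()].
#' @param mask Integer label matrix matching the image dimensions.
#' @param roi_id,patient_id,tissue_type Identity columns stamped on every row;
#'   `tissue_type` is `"tumor"` or `"adjacent"` where known.
#' @return A tibble with columns `cell_id`, `roi_id`, `patient_id`,
#'   `tissue_type`, `centroid_x`, `centroid_y`, `area_px` and one
#'   `raw__<marker>` column per channel.
#' @export
extract_cells <- function(roi, mask, roi_id = roi$roi_id,
                          patient_id = NA_character_,
                          tissue_type = NA_character_) {
  if (!all(dim(mask) == dim(roi$pixels)[1:2]))
    abort("mask dimensions do not match image")
  idx <- which(mask > 0)
  if (length(idx) == 0L) {
    warn("mask contains no labeled pixels; returning empty cell table")
    empty <- tibble(cell_id = integer(), roi_id = character(),
                    patient_id = character(), tissue_type = character(),
                    centroid_x = double(), centroid_y = double(),
                    area_px = integer())
    for (m in roi$channels) empty[[paste0("raw__", m)]] <- double()
    return(empty)
  }
  lab <- mask[idx]
  row0 <- (idx - 1L) %% nrow(mask)        # 0-based row (y)
  col0 <- (idx - 1L) %/% nrow(mask)       # 0-based column (x)
  ids <- sort(unique(lab))
  area <- as.vector(rowsum(rep(1L, length(lab)), lab))
  cx <- as.vector(rowsum(as.numeric(col0), lab)) / area
  cy <- as.vector(rowsum(as.numeric(row0), lab)) / area
  out <- tibble(
    cell_id = as.integer(ids), roi_id = roi_id, patient_id = patient_id,
    tissue_type = tissue_type, centroid_x = cx, centroid_y = cy,
    area_px = as.integer(area)
  )
  npix <- prod(dim(mask))
  for (k in seq_along(roi$channels)) {
    v <- roi$pixels[, , k][idx]
    out[[paste0("raw__", roi$channels[k])]] <- as.vector(rowsum(v, lab)) / area
  }
  out
}

#' Markers present in a cell table
#' @param cells Cell table.
#' @param prefix One of `"raw"`, `"comp"`, `"tfm"`.
#' @return Character vector of marker names.
#' @export
cell_markers <- function(cells, prefix = "raw") {
  pre <- paste0(prefix, "__")
  sub(pre, "", grep(paste0("^", pre), names(cells), value = TRUE), fixed = TRUE)
}

marker_matrix <- function(cells, markers, prefix) {
  cols <- paste0(prefix, "__", markers)
  missing <- setdiff(cols, names(cells))
  if (length(missing))
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  m <- as.matrix(cells[cols])
  colnames(m) <- markers
  m
}

#' Cell-wise spillover compensation
#'
#' Solves, for every cell, `raw = t %*% S` for the true signal `t` under a
#' non-negativity constraint (non-negative least squares): ion counts cannot
#' be negative. Cells whose unconstrained solution is already non-negative
#' take the (identical) direct solve. Markers absent from the spillover
#' matrix pass through unchanged with a warning.
#'
#' @param cells Cell table with `raw__` columns.
#' @param spillover Named square spillover matrix (rows = emitting channel).
#' @return `cells` with added `comp__<marker>` columns and a `comp_residual`
#'   column (Euclidean norm of the per-cell NNLS residual, 0 where the
#'   unconstrained solve was feasible).
#' @export
compensate <- function(cells, spillover) {
  spillover <- validate_spillover(spillover)
  markers <- cell_markers(cells, "raw")
  matched <- intersect(markers, rownames(spillover))
  unmatched <- setdiff(markers, matched)
  if (length(unmatched))
    warn(paste0("markers not in spillover matrix, passed through uncorrected: ",
                paste(unmatched, collapse = ", ")))
  out <- cells
  resid <- rep(0, nrow(cells))
  if (length(matched)) {
    s <- spillover[matched, matched, drop = FALSE]
    raw <- marker_matrix(cells, matched, "raw")
    comp <- raw %*% solve(s)
    bad <- which(apply(comp, 1, function(r) any(r < -1e-10)))
    if (length(bad)) {
      a <- t(s)
      for (i in bad) {
        fit <- pracma::lsqnonneg(a, raw[i, ])
        comp[i, ] <- unname(fit$x)
        resid[i] <- sqrt(max(fit$resid.norm, 0))
      }
    }
    comp[comp < 0 & comp > -1e-10] <- 0
    for (m in matched) out[[paste0("comp__", m)]] <- unname(comp[, m])
  }
  for (m in unmatched) out[[paste0("comp__", m)]] <- cells[[paste0("raw__", m)]]
  out$comp_residual <- resid
  out
}

#' Arcsinh transformation of compensated signals
#'
#' `tfm = asinh(comp / cofactor)`, the variance-stabilizing transform standard
#' in mass cytometry. The default cofactor of 2 suits ion-count data.
#'
#' @param cells Cell table with `comp__` columns.
#' @param cofactor Positive scale divisor.
#' @return `cells` with added `tfm__<marker>` columns.
#' @export
transform_markers <- function(cells, cofactor = 2) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    abort("`cofactor` must be a positive scalar")
  markers <- cell_markers(cells, "comp")
  if (!length(markers)) abort("no comp__ columns; run compensate() first")
  for (m in markers)
    cells[[paste0("tfm__", m)]] <- asinh(cells[[paste0("comp__", m)]] / cofactor)
  cells
}

#' Write / read a cell table
#'
#' Format chosen by extension: `.csv` (readr) or `.parquet` (arrow).
#'
#' @param cells Cell table.
#' @param path Output path.
#' @return `write_cells`: the path, invisibly. `read_cells`: a tibble.
#' @export
write_cells <- function(cells, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the 'arrow' package is required for parquet output")
    arrow::write_parquet(cells, path)
  } else {
    readr::write_csv(cells, path)
  }
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the 'arrow' package is required for parquet input")
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
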