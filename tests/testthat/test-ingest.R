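test_that("TIFF round trip reproduces synthetic pixels and labels exactly", {
  set.seed(11)
  px <- array(as.numeric(rpois(2 * 16, 40)), dim = c(4, 4, 2))
  roi <- roi_image(px, c("CD3", "CD45"), roi_id = "rt")
  mask <- matrix(0L, 4, 4)
  mask[2:3, 2:3] <- 1L
  img_f <- withr::local_tempfile(fileext = ".tiff")
  msk_f <- withr::local_tempfile(fileext = ".tiff")
  write_roi(roi, mask, img_f, msk_f)
  back <- read_roi(img_f, msk_f, panel = c("CD3", "CD45"))
  expect_equal(back$image$pixels, roi$pixels, ignore_attr = TRUE)
  expect_identical(back$mask, mask)
  expect_equal(back$image$channels, c("CD3", "CD45"))

  # contract errors
  bad_mask <- matrix(0L, 5, 5); bad_mask[1, 1] <- 1L
  msk_f2 <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(bad_mask / 65535, msk_f2, bits.per.sample = 16L)
  expect_error(read_roi(img_f, msk_f2, panel = c("CD3", "CD45")), "mask is")
  expect_error(read_roi(img_f, msk_f, panel = c("CD3", "CD45", "CD19")),
               "panel lists")
})

test_that("extract_cells computes per-label means, centroids and areas", {
  # constant-value label
  chA <- matrix(0, 4, 4); chB <- matrix(0, 4, 4)
  mask <- matrix(0L, 4, 4)
  mask[cbind(c(1, 1, 2), c(1, 2, 1))] <- 5L  # 3 px, label id 5
  chA[mask == 5L] <- 5
  roi <- toy_roi(list(A = chA, B = chB))
  cells <- extract_cells(roi, mask)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$cell_id, 5L)
  expect_equal(cells$raw__A, 5)
  expect_equal(cells$raw__B, 0)     # all-zero channel stays 0
  expect_equal(cells$area_px, 3L)

  # hand-derived centroid/mean: pixels (x=0,y=0) value 1 and (x=2,y=0) value 3
  ch <- matrix(0, 3, 3)
  ch[1, 1] <- 1; ch[1, 3] <- 3
  m2 <- matrix(0L, 3, 3); m2[1, 1] <- 1L; m2[1, 3] <- 1L
  c2 <- extract_cells(toy_roi(list(A = ch)), m2)
  expect_equal(c2$raw__A, 2)
  expect_equal(c2$centroid_x, 1)
  expect_equal(c2$centroid_y, 0)
  expect_equal(c2$area_px, 2L)

  expect_warning(e <- extract_cells(toy_roi(list(A = ch)), m2 * 0L), "empty")
  expect_equal(nrow(e), 0L)
})

test_that("total cell area equals the number of nonzero mask pixels", {
  set.seed(21)
  for (rep in 1:5) {
    L <- 40
    mask <- matrix(sample(0:6, L * L, replace = TRUE, prob = c(6, rep(1, 6))),
                   L, L)
    roi <- toy_roi(list(A = matrix(runif(L * L), L, L)))
    cells <- extract_cells(roi, mask)
    expect_identical(sum(cells$area_px), sum(mask > 0))
  }
})

test_that("compensation solves the spillover system", {
  s_id <- diag(2); dimnames(s_id) <- list(c("A", "B"), c("A", "B"))
  cells <- tibble::tibble(cell_id = 1:2, raw__A = c(1, 3), raw__B = c(2, 4))
  out <- compensate(cells, s_id)
  expect_equal(out$comp__A, cells$raw__A)   # identity matrix: no change
  expect_equal(out$comp__B, cells$raw__B)

  s <- matrix(c(1, 0, 0.1, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  solved <- compensate(tibble::tibble(cell_id = 1L, raw__A = 1.0, raw__B = 1.1), s)
  expect_equal(solved$comp__A, 1.0, tolerance = 1e-10)
  expect_equal(solved$comp__B, 1.0, tolerance = 1e-10)

  # infeasible raw -> NNLS with positive residual; checked against grid search
  clipped <- compensate(tibble::tibble(cell_id = 1L, raw__A = 1.0, raw__B = 0.05), s)
  oracle <- grid_nnls2(s, c(1.0, 0.05))
  expect_equal(clipped$comp__A, oracle$x[1], tolerance = 5e-3)
  expect_equal(clipped$comp__B, oracle$x[2], tolerance = 5e-3)
  expect_gt(clipped$comp_residual, 0)

  # unmatched markers pass through with a warning
  expect_warning(
    pass <- compensate(tibble::tibble(cell_id = 1L, raw__A = 1, raw__B = 1,
                                      raw__Zz = 7), s),
    "Zz")
  expect_equal(pass$raw__Zz, pass$comp__Zz)
})

test_that("noiseless spillover mixing is recovered to 1e-8 relative error", {
  set.seed(31)
  n_ch <- 6
  ch <- sprintf("M%d", 1:n_ch)
  s <- diag(n_ch)
  s[cbind(1:(n_ch - 1), 2:n_ch)] <- runif(n_ch - 1, 0.01, 0.08)
  s[cbind(2:n_ch, 1:(n_ch - 1))] <- runif(n_ch - 1, 0.005, 0.03)
  dimnames(s) <- list(ch, ch)
  truth <- matrix(rlnorm(200 * n_ch, 1, 1), 200, n_ch)
  raw <- truth %*% s
  cells <- tibble::as_tibble(setNames(as.data.frame(raw), paste0("raw__", ch)))
  out <- compensate(cells, s)
  comp <- as.matrix(out[paste0("comp__", ch)])
  expect_lt(max(abs(comp - truth) / truth), 1e-8)
})

test_that("arcsinh transform matches the closed form and preserves order", {
  cells <- tibble::tibble(comp__A = c(0, 2, 5, 1000))
  out <- transform_markers(cells, cofactor = 2)
  expect_equal(out$tfm__A[1], 0)
  expect_equal(out$tfm__A[2], log(1 + sqrt(2)))  # asinh(1)
  expect_true(all(diff(out$tfm__A) > 0))
  # order preserved and 0 -> 0 for any cofactor
  for (cf in c(0.5, 2, 10)) {
    t2 <- transform_markers(cells, cofactor = cf)
    expect_equal(t2$tfm__A[1], 0)
    expect_true(all(diff(t2$tfm__A) > 0))
  }
  expect_error(transform_markers(cells, cofactor = 0), "positive")
  expect_error(transform_markers(cells, cofactor = -1), "positive")
})

test_that("cell tables round-trip through csv and parquet", {
  cells <- tibble::tibble(cell_id = 1:3, roi_id = "r", centroid_x = c(1, 2, 3),
                          raw__A = c(0.5, 1.5, 2.5))
  f_csv <- withr::local_tempfile(fileext = ".csv")
  write_cells(cells, f_csv)
  expect_equal(as.data.frame(read_cells(f_csv)), as.data.frame(cells))
  skip_if_not_installed("arrow")
  f_pq <- withr::local_tempfile(fileext = ".parquet")
  write_cells(cells, f_pq)
  expect_equal(as.data.frame(read_cells(f_pq)), as.data.frame(cells))
})

test_that("panel, spillover and gate config files load from extdata", {
  panel <- read_panel(system.file("extdata", "example_panel.csv",
                                  package = "imctme"))
  expect_true(all(c("channel", "marker") %in% names(panel)))
  sp <- read_spillover(system.file("extdata", "example_spillover.csv",
                                   package = "imctme"))
  expect_identical(rownames(sp), panel$marker)
  expect_equal(unname(diag(sp)), rep(1, nrow(sp)))
  gates <- read_gates(system.file("extdata", "example_gates.yaml",
                                  package = "imctme"))
  expect_s3_class(gates$T_cells, "gate_spec")
})
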