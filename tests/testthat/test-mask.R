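test_that("otsu threshold matches brute-force search and handles edge cases", {
  vals <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(vals)
  expect_gt(as.numeric(thr), 0)
  expect_lt(as.numeric(thr), 10)
  expect_identical(attr(thr, "bin"), brute_otsu_bin(vals))

  expect_warning(flat <- otsu_threshold(rep(3, 10)), "constant")
  expect_identical(attr(flat, "bin"), 0L)

  # invariant to duplication of the sample (histogram scaling)
  set.seed(41)
  v <- c(rnorm(100, 2), rnorm(60, 9))
  expect_identical(attr(otsu_threshold(v), "bin"),
                   attr(otsu_threshold(rep(v, 3)), "bin"))
})

test_that("gaussian blur has the right impulse response and conserves mass", {
  delta <- matrix(0, 11, 11); delta[6, 6] <- 1
  b <- gaussian_blur(delta, sigma = 0.8)
  expect_equal(b[6, 6], 1 / (2 * pi * 0.64), tolerance = 1e-3)
  expect_equal(which.max(b), 61L)             # peak stays at center
  expect_equal(sum(b), 1, tolerance = 1e-3)   # interior-supported: mass kept
  const <- matrix(7, 9, 13)
  expect_equal(gaussian_blur(const, 0.8), const)  # reflective boundary
})

test_that("count-based morphology follows the ImageJ neighbor rules", {
  # single isolated pixel erodes away; dilates to a 3x3 block
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_false(any(binary_morph(single, "erode", 1, 1)))
  d <- binary_morph(single, "dilate", 1, 1)
  expect_identical(sum(d), 9L)
  expect_true(all(d[2:4, 2:4]))

  # 3x3 solid block, erode count 1: only the center survives
  block <- matrix(FALSE, 5, 5); block[2:4, 2:4] <- TRUE
  e <- binary_morph(block, "erode", 1, 1)
  expect_identical(which(e), which(matrix(seq_len(25), 5, 5) == 13))

  # dilation is extensive, erosion anti-extensive, open within dilated input
  set.seed(51)
  for (rep in 1:10) {
    m <- rand_mask(20, 20, 0.4)
    eroded <- binary_morph(m, "erode", 2, 1)
    dilated <- binary_morph(m, "dilate", 2, 1)
    expect_false(any(eroded & !m))    # erode(m) subset of m
    expect_false(any(m & !dilated))   # m subset of dilate(m)
  }
})

test_that("morphology matches the literal per-pixel oracle", {
  set.seed(52)
  for (rep in 1:25) {
    m <- rand_mask(14, 14, runif(1, 0.2, 0.7))
    op <- sample(c("erode", "dilate"), 1)
    it <- sample(1:3, 1)
    cnt <- sample(1:8, 1)
    expect_identical(binary_morph(m, op, it, cnt),
                     brute_morph(m, op, it, cnt),
                     info = sprintf("%s it=%d count=%d rep=%d", op, it, cnt, rep))
  }
})

test_that("small-object removal respects the size boundary and 8-connectivity", {
  # 199 px removed, 200 px kept
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:21] <- TRUE            # 200 px component
  m2 <- m; m2[11, 21] <- FALSE     # 199 px
  expect_true(all(remove_small_objects(m, 200) == m))
  expect_false(any(remove_small_objects(m2, 200)))
  # touching diagonal pixels are one object under 8-connectivity
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_true(all(remove_small_objects(diagm, 2) == diagm))
  expect_false(any(remove_small_objects(diagm, 3)))
  expect_false(any(remove_small_objects(matrix(FALSE, 3, 3), 5)))
  # random masks match the flood-fill oracle
  set.seed(53)
  for (rep in 1:20) {
    m <- rand_mask(16, 16, runif(1, 0.3, 0.7))
    k <- sample(2:12, 1)
    expect_identical(remove_small_objects(m, k), brute_remove_small(m, k))
  }
})

test_that("the distance transform is exact", {
  expect_true(all(edt(matrix(TRUE, 4, 4)) == 0))
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  d <- edt(m)
  expect_equal(d[1, 1], 2 * sqrt(2))
  expect_equal(d[1, 3], 2)
  expect_warning(nan <- edt(matrix(FALSE, 3, 3)), "no foreground")
  expect_true(all(is.nan(nan)))
  # exact equality of squared distances with brute force
  set.seed(54)
  for (rep in 1:15) {
    m <- rand_mask(32, 32, runif(1, 0.02, 0.3))
    if (!any(m)) m[1, 1] <- TRUE
    expect_identical(edt(m, squared = TRUE), brute_edt_sq(m))
  }
})

test_that("build_tumor_mask recovers a bright blob through the macro pipeline", {
  sim <- simulate_mask_roi(size = 256, radius = 45, snr = 8, seed = 3)
  tm <- suppressMessages(build_tumor_mask(sim$image))
  # one component covering the blob plus at most a 9 px dilation rim
  expect_identical(max(label_components(tm$mask)), 1L)
  expect_gte(mean(tm$mask[sim$truth]), 0.99)
  # count-based dilation grows diagonally too: 9 iterations reach at most
  # 9 * sqrt(2) px from the pre-dilation boundary
  dist_out <- edt(sim$truth)
  expect_true(all(dist_out[tm$mask & !sim$truth] <= 9 * sqrt(2) + 1))
  # distance map: zero exactly on the mask, positive elsewhere
  expect_true(all(tm$distance_map[tm$mask] == 0))
  expect_true(all(tm$distance_map[!tm$mask] > 0))

  # degenerate: flat image -> empty mask, NaN distance map
  zero <- roi_image(array(0, c(16, 16, 2)), c("CK18", "aSMA"))
  expect_warning(tz <- build_tumor_mask(zero), "flat|empty")
  expect_false(any(tz$mask))
  expect_true(all(is.nan(tz$distance_map)))
  expect_error(build_tumor_mask(sim$image, channels = c("CK18", "CD3")),
               "CD3")
})

test_that("the macro equals its standalone stages composed in sequence", {
  sim <- simulate_mask_roi(size = 128, radius = 30, snr = 6, seed = 9)
  comp <- roi_channel(sim$image, "CK18") + roi_channel(sim$image, "aSMA")
  blurred <- gaussian_blur(comp, 0.8)
  thr <- otsu_threshold(blurred)
  m <- blurred >= as.numeric(thr)
  m <- binary_open(m, 5, 1)
  m <- remove_small_objects(m, 200)
  m <- binary_morph(m, "dilate", 9, 1)
  tm <- suppressMessages(build_tumor_mask(sim$image))
  expect_identical(tm$mask, m)
  expect_equal(tm$distance_map, edt(m))
})

test_that("cells map onto tumor mask and distance map by rounded centroid", {
  mask <- matrix(FALSE, 10, 10)
  mask[, 1:3] <- TRUE   # tumor = columns x in 0..2
  tm <- structure(list(roi_id = "t", mask = mask, distance_map = edt(mask),
                       threshold = 1), class = "tumor_mask")
  cells <- tibble::tibble(cell_id = 1:3,
                          centroid_x = c(1.2, 5.0, 2.4), centroid_y = c(4, 4, 9))
  out <- assign_tissue_region(cells, tm)
  expect_identical(out$in_tumor, c(TRUE, FALSE, TRUE))
  expect_equal(out$distance_to_tumor, c(0, 3, 0))  # 3 px right of the edge
  expect_identical(out$region, c("tumor", "stroma", "tumor"))
  # out-of-bounds centroid clamps with a warning
  expect_warning(
    clamp <- assign_tissue_region(
      tibble::tibble(cell_id = 1L, centroid_x = 12.7, centroid_y = -0.9), tm),
    "clamped")
  expect_identical(clamp$in_tumor, FALSE)
})
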