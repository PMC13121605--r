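test_that("nearest-member distances are Euclidean within ROI", {
  cells <- toy_cells(x = c(0, 3, 10, 50), y = c(0, 4, 0, 50),
                     cluster = c("ref", "tar", "tar", "lone"))
  d <- nn_distance_to_cluster(cells, "ref", "tar")
  expect_equal(d$nearest_distance_px, 5)  # min(5, 10)

  # co-located reference and target: distance 0 (different cells)
  co <- toy_cells(x = c(2, 2), y = c(3, 3), cluster = c("ref", "tar"))
  expect_equal(nn_distance_to_cluster(co, "ref", "tar")$nearest_distance_px, 0)

  # a cell in both roles never matches itself
  both <- toy_cells(x = c(0, 9), y = c(0, 0), cluster = c("dual", "dual"))
  dd <- nn_distance_to_cluster(both, "dual", "dual")
  expect_equal(dd$nearest_distance_px, c(9, 9))

  # target absent from the ROI: NA, excluded from pooled median
  two_roi <- dplyr::bind_rows(
    toy_cells(x = c(0, 1), y = c(0, 0), cluster = c("ref", "tar"),
              roi_id = "A"),
    toy_cells(x = 0, y = 0, cluster = "ref", roi_id = "B", cell_id = 10L)
  )
  d2 <- nn_distance_to_cluster(two_roi, "ref", "tar")
  expect_identical(sum(is.na(d2$nearest_distance_px)), 1L)
  expect_equal(median(d2$nearest_distance_px, na.rm = TRUE), 1)
  expect_warning(empty <- nn_distance_to_cluster(two_roi, "nope", "tar"),
                 "no reference")
  expect_identical(nrow(empty), 0L)
})

test_that("radius counts use an inclusive boundary in microns", {
  cells <- toy_cells(x = c(0, 19.9, 20.1, 0), y = c(0, 0, 0, 20),
                     cluster = c("ref", "tar", "tar", "tar"))
  n <- neighbors_within(cells, "ref", "tar", radius_um = 20, pixel_size_um = 1)
  expect_identical(n$n_within_radius, 2L)  # 19.9 and exactly 20 in; 20.1 out

  # pixel size rescales the radius: 20 um at 2 um/px = 10 px
  n2 <- neighbors_within(cells, "ref", "tar", radius_um = 20,
                         pixel_size_um = 2)
  expect_identical(n2$n_within_radius, 0L)

  # radius 0 counts only exact co-location
  co <- toy_cells(x = c(5, 5, 6), y = c(5, 5, 5),
                  cluster = c("ref", "tar", "tar"))
  expect_identical(neighbors_within(co, "ref", "tar",
                                    radius_um = 0)$n_within_radius, 1L)
})

test_that("radius counts equal the all-pairs brute force", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 200
    cells <- toy_cells(
      x = runif(n, 0, 300), y = runif(n, 0, 300),
      cluster = sample(c("a", "b", "c"), n, replace = TRUE),
      roi_id = sample(c("R1", "R2"), n, replace = TRUE)
    )
    cells$cell_id <- seq_len(n)
    got <- neighbors_within(cells, "a", "b", radius_um = 25)
    want <- brute_neighbors_within(cells, "a", "b", 25)
    ref_order <- order(cells$roi_id[cells$cluster == "a"])
    expect_identical(got$n_within_radius, want[ref_order])
  }
})

test_that("neighborhood comparison ranks targets and tests distances", {
  set.seed(62)
  # near targets at ~1-3 px, far targets at ~100 px
  ref <- toy_cells(x = runif(30, 100, 110), y = runif(30, 100, 110),
                   cluster = "ref")
  near <- toy_cells(x = runif(25, 100, 112), y = runif(25, 100, 112),
                    cluster = "near", cell_id = 100 + 1:25)
  far <- toy_cells(x = runif(25, 0, 10), y = runif(25, 0, 10),
                   cluster = "far", cell_id = 200 + 1:25)
  cells <- dplyr::bind_rows(ref, near, far)
  cmp <- compare_neighborhoods(cells, "ref", radius_um = 20)
  expect_identical(cmp$summary$target_cluster[1], "near")
  expect_lt(cmp$summary$median_distance_px[1],
            cmp$summary$median_distance_px[2])
  expect_gt(cmp$summary$mean_n_within_radius[1],
            cmp$summary$mean_n_within_radius[2])
  expect_lt(cmp$tests$p_adj[1], 0.01)
  expect_identical(nrow(tidy(cmp)), 2L)

  # identical distance sets: p in the no-evidence region
  sym <- dplyr::bind_rows(
    toy_cells(x = 0, y = 0, cluster = "ref"),
    toy_cells(x = c(3, -3), y = c(0, 0), cluster = c("t1", "t2"),
              cell_id = 5:6)
  )
  cmp2 <- compare_neighborhoods(sym, "ref")
  expect_gte(cmp2$tests$p_value[1], 0.9)

  # targets never co-occurring with the reference drop from the summary
  ghost <- dplyr::bind_rows(
    cells,
    toy_cells(x = 1, y = 1, cluster = "ghost", roi_id = "elsewhere",
              cell_id = 999L)
  )
  cmp3 <- compare_neighborhoods(ghost, "ref", radius_um = 20)
  expect_false("ghost" %in% cmp3$summary$target_cluster)
})

test_that("synthetic attraction shows up as shorter nearest distances", {
  sc <- default_scenario(seed = 101)
  sim <- simulate_roi(sc, roi_index = 1, tissue = "adjacent", render = FALSE)
  cells <- sim$cells
  cells$cluster <- cells$population
  # offspring scatter around parents, so each child is near *a* parent;
  # B has the parent population's abundance but no interaction
  d_child <- nn_distance_to_cluster(cells, sc$attraction$child,
                                    sc$attraction$parent)
  d_indep <- nn_distance_to_cluster(cells, sc$attraction$child, "B")
  expect_lt(median(d_child$nearest_distance_px, na.rm = TRUE),
            median(d_indep$nearest_distance_px, na.rm = TRUE))
})
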