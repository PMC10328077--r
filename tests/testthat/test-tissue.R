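test_that("Otsu threshold separates two-level and bimodal images", {
  # half 10s, half 200s: any separating threshold; must match the
  # exhaustive maximizer
  img <- matrix(c(rep(10, 200), rep(200, 200)), 20, 20)
  th <- otsu_threshold(img)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_equal(th, otsu_exhaustive(img), tolerance = (200 - 10) / 256)
  # bimodal Gaussian mixture: within one bin of the exhaustive maximizer
  set.seed(41)
  v <- matrix(c(rnorm(3000, 30, 10), rnorm(3000, 180, 10)), 60, 100)
  bin_w <- diff(range(v)) / 256
  expect_lt(abs(otsu_threshold(v) - otsu_exhaustive(v)), bin_w + 1e-9)
  # constant image errors
  expect_error(otsu_threshold(matrix(5, 10, 10)), "constant")
})

test_that("Otsu threshold is invariant under affine intensity rescaling", {
  set.seed(42)
  v <- matrix(c(rnorm(2000, 40, 8), rnorm(2000, 150, 12)), 40, 100)
  th <- otsu_threshold(v)
  th2 <- otsu_threshold(3 * v + 17)
  bin_w <- diff(range(3 * v + 17)) / 256
  expect_lt(abs(th2 - (3 * th + 17)), bin_w + 1e-9)
})

test_that("mask cleanup enforces the strict 50-pixel area rule", {
  cfg <- pipeline_config()
  # 49-px component removed, 50-px kept (7x7 square = 49; 5x10 = 50)
  m49 <- matrix(0, 30, 30); m49[2:8, 2:8] <- 1
  expect_equal(max(clean_mask(m49, cfg)), 0)
  m50 <- matrix(0, 30, 30); m50[2:6, 2:11] <- 1
  lab <- clean_mask(m50, cfg)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 50)
})

test_that("holes are filled before the area filter", {
  cfg <- pipeline_config()
  # ring of 100 px around a 20-px hole: filled to 120 px
  m <- matrix(0, 30, 30)
  m[6:15, 6:17] <- 1          # 10 x 12 = 120 block
  m[9:12, 9:13] <- 0          # 4 x 5 = 20 hole -> ring of 100
  expect_equal(sum(m), 100)
  lab <- clean_mask(m, cfg)
  expect_equal(sum(lab == 1), 120)
})

test_that("labeling uses 8-connectivity", {
  cfg <- pipeline_config(area_min_px = 1)
  m <- matrix(0, 20, 20)
  m[2:6, 2:6] <- 1            # 25 px
  m[7:11, 7:11] <- 1          # diagonal touch at (6,6)-(7,7)
  lab <- clean_mask(m, cfg)
  expect_equal(max(lab), 1)   # one 8-connected object
})

test_that("cell ROIs are 100-px boxes clipped at borders", {
  cfg <- pipeline_config()
  lab <- matrix(0L, 512, 512)
  lab[251:260, 251:260] <- 1L   # centroid ~ image centre
  rois <- cell_rois(lab, cfg)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$height, 100)
  expect_equal(rois$width, 100)
  # centroid 10 px from the left edge: clipped box
  lab2 <- matrix(0L, 200, 200)
  lab2[96:105, 6:15] <- 1L
  rois2 <- cell_rois(lab2, cfg)
  expect_lt(rois2$width, 100)
  expect_equal(rois2$col0, 0)
  # three labels give three ROIs
  lab3 <- matrix(0L, 300, 300)
  lab3[11:20, 11:20] <- 1L; lab3[111:120, 111:120] <- 2L
  lab3[211:220, 211:220] <- 3L
  expect_equal(nrow(cell_rois(lab3, cfg)), 3)
})

test_that("ROI correlation handles identity, inversion and degeneracy", {
  set.seed(43)
  a <- matrix(rnorm(400), 20, 20)
  expect_equal(roi_channel_correlation(a, a), 1)
  expect_equal(roi_channel_correlation(a, 10 - a), -1)
  expect_warning(r <- roi_channel_correlation(a, matrix(3, 20, 20)),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("independent channels give near-zero ROI correlation", {
  inside <- 0
  for (i in 1:200) {
    set.seed(i)
    r <- roi_channel_correlation(matrix(rnorm(10000), 100),
                                 matrix(rnorm(10000), 100))
    if (abs(r) < 0.05) inside <- inside + 1
  }
  expect_gte(inside / 200, 0.95)
})

test_that("summed intensity is background-corrected and clipped", {
  expect_equal(roi_summed_intensity(matrix(30, 10, 10), 30), 0)
  expect_equal(roi_summed_intensity(matrix(35, 10, 10), 30), 500)
  # mode-based background estimate
  v <- c(rep(20, 900), rep(200, 100))
  expect_equal(channel_background(matrix(v, 10, 100)), 20,
               tolerance = (200 - 20) / 256)
  # synthetic spot of known photon sum on flat background
  fr <- single_spot_frame(12.4, 12.6, photon_scale = 8000,
                          background = 50, size = 25)
  expect_equal(roi_summed_intensity(fr, 50), 8000, tolerance = 80)
})

test_that("full tissue analysis recovers every generated nucleus once", {
  ti <- simulate_tissue_image(width = 256, height = 256, n_nuclei = 8,
                              radius_range = c(6, 10), alpha = 0.6,
                              seed = 44)
  res <- analyze_tissue(ti$channels, "nuclei")
  big <- ti$truth[ti$truth$area_px >= 50, ]
  expect_equal(nrow(res), nrow(big))
  # each recovered centroid near a distinct true centre
  d <- sqrt(outer(res$x, big$x, "-")^2 + outer(res$y, big$y, "-")^2)
  expect_true(all(apply(d, 1, min) < 2))
  expect_equal(anyDuplicated(apply(d, 1, which.min)), 0)
  # sub-50-px objects absent
  ti2 <- simulate_tissue_image(width = 200, height = 200, n_nuclei = 6,
                               radius_range = c(3, 3), seed = 45)
  expect_true(all(ti2$truth$area_px < 50))
  th <- otsu_threshold(ti2$channels$nuclei)
  expect_equal(max(clean_mask(ti2$channels$nuclei > th,
                              pipeline_config())), 0)
})
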