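test_that("candidate finding behaves on flat, single- and two-spot frames", {
  cfg <- pipeline_config()
  # flat frame: no candidates
  expect_equal(nrow(find_candidates(matrix(7, 30, 30), cfg)), 0)
  # one bright spot: exactly one seed within 1 px of truth
  fr <- single_spot_frame(14.4, 12.8, photon_scale = 20000,
                          background = 20, read_noise = 2, noise = TRUE,
                          size = 30, seed = 2)
  cand <- find_candidates(fr, cfg)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$x - 14.4)^2 + (cand$y - 12.8)^2), 1)
  # two spots 10 px apart: two seeds
  cfg2 <- sim_config(image_width = 40, image_height = 30, n_frames = 1,
                     photon_scale = 20000, background_rate = 20,
                     read_noise_sigma = 2,
                     spot_specs = data.frame(x = c(12, 22), y = c(15, 15),
                                             n_fluor = 1,
                                             channel = "green"),
                     seed = 3)
  fr2 <- simulate_tirf_stack(cfg2)$stacks$green$frames[[1]]
  expect_equal(nrow(find_candidates(fr2, cfg)), 2)
})

test_that("iterative Gaussian masking localizes noiseless spots", {
  cfg <- pipeline_config()
  # symmetric spot on a pixel centre: exact centroid by symmetry
  fr <- single_spot_frame(12, 12)
  roi <- smstoich:::extract_roi(fr, 12, 12, cfg$roi_halfwidth)
  fit <- iterative_gaussian_mask(roi$values, c(8, 8), cfg)
  expect_true(fit$converged)
  expect_equal(fit$centroid, c(8, 8), tolerance = 1e-9)
  # off-centre spot: centroid within 0.05 px of a least-squares fit
  fr2 <- single_spot_frame(12.30, 11.80)
  roi2 <- smstoich:::extract_roi(fr2, 12, 12, cfg$roi_halfwidth)
  fit2 <- iterative_gaussian_mask(roi2$values, c(8, 8), cfg)
  ls <- fit_gaussian_ls(roi2$values)
  expect_lt(sqrt(sum((fit2$centroid - ls)^2)), 0.05)
  # uniform roi: degenerate flag, centroid = seed
  fitu <- iterative_gaussian_mask(matrix(4, 17, 17), c(8, 8), cfg)
  expect_true(fitu$degenerate)
  expect_equal(fitu$centroid, c(8, 8))
  # seed outside roi errors
  expect_error(iterative_gaussian_mask(matrix(1, 17, 17), c(30, 8), cfg),
               "seed")
})

test_that("masking is idempotent at convergence", {
  cfg <- pipeline_config()
  fr <- single_spot_frame(12.41, 12.07)
  roi <- smstoich:::extract_roi(fr, 12, 12, cfg$roi_halfwidth)
  fit <- iterative_gaussian_mask(roi$values, c(8, 8), cfg)
  refit <- iterative_gaussian_mask(roi$values, fit$centroid, cfg)
  expect_lt(sqrt(sum((refit$centroid - fit$centroid)^2)),
            cfg$convergence_tol_px)
})

test_that("focus photometry recovers the true photon count", {
  cfg <- pipeline_config()
  # noiseless spot of known total count on flat background
  fr <- single_spot_frame(12.3, 11.7, photon_scale = 5000,
                          background = 50)
  f <- measure_focus(fr, c(12.3, 11.7), cfg, frame_index = 4L)
  expect_equal(f$frame, 4L)
  expect_equal(f$intensity, 5000, tolerance = 0.01)
  expect_equal(f$background, 50, tolerance = 1e-6)
  # all-background roi: zero intensity, rejected downstream
  fb <- measure_focus(matrix(50, 40, 40), c(20, 20), cfg)
  expect_equal(fb$intensity, 0)
  expect_false(accept_focus(fb, cfg))
  expect_equal(fb$snr, 0)
  # zero-variance ring around real signal gives the documented sentinel
  frs <- matrix(50, 41, 41); frs[21, 21] <- 5050
  fs <- measure_focus(frs, c(20, 20), cfg)
  expect_equal(fs$snr, Inf)
  expect_true(accept_focus(fs, cfg))
  # edge spot: no full roi support
  expect_null(measure_focus(fr, c(2, 2), cfg))
})

test_that("photometric linearity holds across fluorophore numbers", {
  cfg <- pipeline_config()
  for (n in c(1, 3, 10)) {
    fr <- single_spot_frame(12.2, 12.6, n_fluor = n, photon_scale = 2000,
                            background = 30)
    f <- measure_focus(fr, c(12.2, 12.6), cfg)
    expect_equal(f$intensity / (n * 2000), 1, tolerance = 0.02)
  }
})

test_that("the SNR acceptance threshold is strict", {
  cfg <- pipeline_config()
  f <- data.frame(snr = 0.4)
  expect_false(accept_focus(f, cfg))
  f$snr <- 0.41
  expect_true(accept_focus(f, cfg))
  f$snr <- 0.39
  expect_false(accept_focus(f, cfg))
  f$snr <- 5
  expect_true(accept_focus(f, cfg))
})

test_that("noiseless localization error is below 0.05 px RMS", {
  cfg <- pipeline_config()
  set.seed(11)
  err2 <- replicate(40, {
    x <- 12 + runif(1, -0.5, 0.5)
    y <- 12 + runif(1, -0.5, 0.5)
    fr <- single_spot_frame(x, y)
    cand <- find_candidates(fr, cfg)
    roi <- smstoich:::extract_roi(fr, cand$x[1], cand$y[1],
                                  cfg$roi_halfwidth)
    fit <- iterative_gaussian_mask(
      roi$values, c(cand$x[1] - roi$x0, cand$y[1] - roi$y0), cfg)
    sum((fit$centroid + c(roi$x0, roi$y0) - c(x, y))^2)
  })
  expect_lt(sqrt(mean(err2)), 0.05)
})
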