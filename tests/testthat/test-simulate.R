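test_that("identical config and seed give bit-identical stacks", {
  spec <- data.frame(x = c(10.2, 25.7), y = c(12.1, 20.4),
                     n_fluor = c(2, 5), channel = "green")
  cfg <- sim_config(image_width = 40, image_height = 40, n_frames = 5,
                    spot_specs = spec, seed = 42)
  a <- simulate_tirf_stack(cfg)
  b <- simulate_tirf_stack(cfg)
  expect_identical(a$stacks$green$frames, b$stacks$green$frames)
  expect_identical(a$truth, b$truth)
})

test_that("expectation mode conserves photons exactly", {
  # one unbleachable fluorophore, no background, no noise: every frame
  # sums to the per-fluorophore photon scale
  fr <- single_spot_frame(12.3, 11.6, photon_scale = 7000)
  expect_equal(sum(fr), 7000, tolerance = 1e-6)
  # spot centred on a pixel: peak at that pixel
  fr2 <- single_spot_frame(12, 12)
  expect_equal(which.max(fr2), which(row(fr2) == 13 & col(fr2) == 13))
})

test_that("pure background has the configured Poisson mean and variance", {
  cfg <- sim_config(image_width = 120, image_height = 120, n_frames = 10,
                    background_rate = 100, read_noise_sigma = 0, seed = 7)
  s <- simulate_tirf_stack(cfg)
  px <- unlist(s$stacks$green$frames)
  se <- sqrt(100 / length(px))
  expect_lt(abs(mean(px) - 100), 3 * se)
  # variance ~ mean for Poisson counts (>= 1e5 pixels)
  expect_gt(length(px), 1e5)
  expect_lt(abs(var(px) - mean(px)) / mean(px), 0.02)
})

test_that("per-fluorophore bleaching follows the binomial expectation", {
  set.seed(3)
  surv <- smstoich:::simulate_survival(rep(5L, 1000), 0.1, 15)
  # monotone non-increasing, starts at N
  expect_true(all(surv[1, ] == 5))
  expect_true(all(apply(surv, 2, function(s) all(diff(s) <= 0))))
  # closed-form binomial expectation oracle: E n_t = 5 * 0.9^t
  for (t in c(3, 8, 15)) {
    expected <- 5 * 0.9^(t - 1)
    sd_mean <- sqrt(5 * 0.9^(t - 1) * (1 - 0.9^(t - 1)) / 1000)
    expect_lt(abs(mean(surv[t, ]) - expected), 4 * sd_mean)
  }
})

test_that("invalid simulation parameters are rejected", {
  spec_out <- data.frame(x = 100, y = 5, n_fluor = 1, channel = "green")
  expect_error(sim_config(image_width = 40, image_height = 40,
                          spot_specs = spec_out), "inside the image")
  expect_error(sim_config(background_rate = -1), "background_rate")
  expect_error(sim_config(bleach_prob = 1.5), "bleach_prob")
  expect_error(sim_config(colocalized_fraction = -0.1),
               "colocalized_fraction")
})

test_that("simulate_trace reproduces forced and stochastic bleach steps", {
  tr <- simulate_trace(2, 100, bleach_frames = c(10, 20), n_frames = 30)
  expect_equal(tr$values[1:10], rep(200, 10))
  expect_equal(tr$values[11:20], rep(100, 10))
  expect_equal(tr$values[21:30], rep(0, 10))
  expect_equal(tr$bleach_frames, c(10L, 20L))
  # constant when nothing bleaches
  expect_equal(simulate_trace(1, 50, n_frames = 10)$values, rep(50, 10))
  # expectation oracle: mean trace over replicates decays as N nu (1-p)^t
  nu <- 10
  traces <- vapply(1:500, function(i)
    simulate_trace(10, nu, bleach_prob = 0.05, noise_sigma = nu / 10,
                   n_frames = 40, seed = i)$values, numeric(40))
  t_check <- c(10, 25, 40)
  for (t in t_check) {
    expected <- 10 * nu * 0.95^(t - 1)
    # binomial variance + measurement noise, over 500 replicates
    v <- 10 * 0.95^(t - 1) * (1 - 0.95^(t - 1)) * nu^2 + (nu / 10)^2
    expect_lt(abs(mean(traces[t, ]) - expected), 4 * sqrt(v / 500))
  }
})

test_that("tissue simulator controls correlation and records disc areas", {
  # alpha = 1: channel B equals channel A exactly, correlation 1
  ti <- simulate_tissue_image(n_nuclei = 3, alpha = 1, seed = 5)
  expect_equal(cor(as.numeric(ti$channels$chA), as.numeric(ti$channels$chB)),
               1, tolerance = 1e-12)
  # alpha = 0: independent fields, near-zero correlation over the image
  ti0 <- simulate_tissue_image(n_nuclei = 3, alpha = 0, seed = 5)
  expect_lt(abs(cor(as.numeric(ti0$channels$chA),
                    as.numeric(ti0$channels$chB))), 0.02)
  # rasterized disc area oracle from the recorded centres and radii
  ti3 <- simulate_tissue_image(width = 128, height = 128, n_nuclei = 4,
                               radius_range = c(3, 3), seed = 9)
  for (i in seq_len(4)) {
    xs <- outer(rep(1, 128), 0:127); ys <- outer(0:127, rep(1, 128))
    oracle <- sum((xs - ti3$truth$x[i])^2 + (ys - ti3$truth$y[i])^2 <= 9)
    expect_equal(ti3$truth$area_px[i], oracle)
    expect_lt(ti3$truth$area_px[i], 50)  # below the nucleus area filter
  }
})

test_that("infeasible nuclei packing raises an error", {
  expect_error(
    simulate_tissue_image(width = 64, height = 64, n_nuclei = 50,
                          radius_range = c(10, 12), seed = 1),
    "cannot pack")
})
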