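test_that("Chung-Kennedy filter passes constants and noiseless steps through", {
  expect_equal(chung_kennedy_filter(rep(7.5, 40)), rep(7.5, 40))
  x <- c(rep(100, 50), rep(0, 50))
  expect_equal(chung_kennedy_filter(x), x)
  expect_error(chung_kennedy_filter(numeric(0)), "empty")
})

test_that("Chung-Kennedy filter matches its direct reference evaluation", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    x <- cumsum(rnorm(n)) + rnorm(n)
    got <- chung_kennedy_filter(x, windows = c(2, 4, 8), weight_exponent = 2)
    want <- ck_reference(x, windows = c(2, 4, 8), p = 2)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("filtering reduces plateau variance without displacing steps", {
  set.seed(22)
  x <- c(rep(100, 50), rep(0, 50)) + rnorm(100, sd = 10)
  f <- chung_kennedy_filter(x)
  expect_lt(var(f[10:40]), var(x[10:40]))
  expect_lt(var(f[60:90]), var(x[60:90]))
  st <- detect_steps(f)
  expect_equal(nrow(st), 1)
  expect_lte(abs(st$frame - 50), 2)
})

test_that("step detection finds noiseless single and double steps exactly", {
  x1 <- c(rep(100, 50), rep(0, 50))
  st1 <- detect_steps(x1)
  expect_equal(st1$frame, 50)
  expect_equal(st1$size, 100)
  x2 <- c(rep(200, 30), rep(100, 30), rep(0, 40))
  st2 <- detect_steps(x2)
  expect_equal(st2$frame, c(30, 60))
  expect_equal(st2$size, c(100, 100))
  # flat trace: no steps
  expect_equal(nrow(detect_steps(rep(5, 30))), 0)
})

test_that("noisy steps are recovered within two frames", {
  hits <- 0
  for (i in 1:200) {
    set.seed(i)
    x <- c(rep(50, 40), rep(0, 40)) + rnorm(80, sd = 10)  # step:noise 5:1
    st <- detect_steps(chung_kennedy_filter(x))
    if (nrow(st) >= 1 && any(abs(st$frame - 40) <= 2)) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("characteristic intensity estimates the single-dye mode", {
  expect_equal(characteristic_intensity(rep(10, 20)), 10)
  set.seed(23)
  v <- rnorm(500, 10, 1)
  est <- characteristic_intensity(v)
  expect_gt(est, 9.5); expect_lt(est, 10.5)
  # dominant mode wins over the mixture mean
  bim <- c(rnorm(400, 10, 0.5), rnorm(100, 20, 0.5))
  est2 <- characteristic_intensity(bim)
  expect_lt(abs(est2 - 10), 1)
  expect_error(characteristic_intensity(numeric(0)), "simulate_trace")
})

test_that("photobleach correction uses exact OLS on the first points", {
  # collinear points: exact intercept
  est <- estimate_stoichiometry(c(100, 90, 80, 70), 0, 10)
  expect_equal(est$initial_intensity, 100)
  expect_equal(est$stoichiometry, 10)
  # constant trace at the single-dye intensity: S = 1
  est1 <- estimate_stoichiometry(rep(10, 6), 0, 10)
  expect_equal(est1$stoichiometry, 1)
  # 10 %/frame exponential decay: hand-computed OLS through
  # {200, 180, 162, 145.8} has intercept 199.04, within 2% of 200
  y <- c(200, 180, 162, 145.8)
  xbar <- 1.5; ybar <- mean(y)
  slope <- sum((0:3 - xbar) * (y - ybar)) / sum((0:3 - xbar)^2)
  hand <- ybar - slope * xbar
  est2 <- estimate_stoichiometry(y, 0, 10)
  expect_equal(est2$initial_intensity, hand, tolerance = 1e-12)
  expect_equal(hand, 199.04, tolerance = 1e-9)
  expect_lt(abs(est2$initial_intensity - 200) / 200, 0.02)
  # OLS matches lm to machine precision on random traces
  set.seed(24)
  for (i in 1:5) {
    v <- rnorm(4, 100, 10)
    est3 <- estimate_stoichiometry(v, 0, 1)
    expect_equal(est3$initial_intensity,
                 unname(coef(lm(v ~ t, data.frame(v = v, t = 0:3)))[1]),
                 tolerance = 1e-10)
  }
})

test_that("stoichiometry eligibility rules are strict and non-fatal", {
  # start frame 9 eligible, 10 excluded (0-based, first 10 frames)
  expect_false(estimate_stoichiometry(c(40, 40, 40, 40), 9, 10)$excluded)
  est <- estimate_stoichiometry(c(40, 40, 40, 40), 10, 10)
  expect_true(est$excluded)
  expect_equal(est$reason, "late_start")
  # too-short tracks are excluded with a reason, not errored
  est2 <- estimate_stoichiometry(c(40, 40, 40), 0, 10)
  expect_true(est2$excluded)
  expect_equal(est2$reason, "short_track")
  expect_error(estimate_stoichiometry(c(40, 40, 40, 40), 0, 0), "i_single")
})

test_that("stoichiometry is invariant under intensity rescaling", {
  set.seed(25)
  v <- 100 * 0.95^(0:9) + rnorm(10, sd = 1)
  s1 <- estimate_stoichiometry(v, 0, 10)$stoichiometry
  s2 <- estimate_stoichiometry(v * 37, 0, 370)$stoichiometry
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("single-dye calibration recovers the fluorophore intensity", {
  set.seed(26)
  nu <- 100
  traces <- lapply(1:60, function(i) {
    tr <- simulate_trace(sample(1:3, 1), nu, bleach_prob = 0.05,
                        noise_sigma = nu / 10, n_frames = 80)
    list(frames = 0:79, values = tr$values)
  })
  cand <- single_dye_intensities(traces, n_frames = 80)
  expect_gt(length(cand), 10)
  est <- characteristic_intensity(cand)
  expect_lt(abs(est - nu) / nu, 0.15)
})
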