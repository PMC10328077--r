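#' Image stack container
#'
#' Lightweight container for an ordered sequence of equally sized frames
#' from one fluorescence channel.
#'
#' @param frames List of numeric matrices (rows = y, columns = x), all of
#'   identical dimensions, with non-negative intensities.
#' @param channel Channel label, e.g. `"green"`.
#' @param pixel_size Pixel size in nm.
#' @param frame_interval Frame interval in ms.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, channel = "green", pixel_size = 100,
                        frame_interval = 50) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("frame intensities must be non-negative")
  structure(
    list(frames = frames, channel = channel, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> channel=%s, %d frames of %dx%d px, %g nm/px, %g ms/frame\n",
    x$channel, length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

# Fraction of a unit-intensity integrated Gaussian falling into pixels with
# 0-based centers `idx` along one axis, for a source at `center`.
psf_profile <- function(idx, center, sigma) {
  stats::pnorm(idx + 0.5, mean = center, sd = sigma) -
    stats::pnorm(idx - 0.5, mean = center, sd = sigma)
}

# Additive rendering of one spot's PSF patch into an expected-value image.
# Returns the image; patch support is truncated at +-ceiling(6*sigma).
add_spot <- function(img, x, y, photons, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(6 * sigma)
  cols <- max(0, floor(x) - r):min(w - 1, ceiling(x) + r)
  rows <- max(0, floor(y) - r):min(h - 1, ceiling(y) + r)
  patch <- photons * outer(psf_profile(rows, y, sigma),
                           psf_profile(cols, x, sigma))
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + patch
  img
}

# Per-fluorophore survival counts: n_frames x n_spots matrix, row t holding
# the number of unbleached fluorophores during frame t (1-based rows for
# 0-based frames t-1).  Bleaching is irreversible binomial thinning.
simulate_survival <- function(n_fluor, bleach_prob, n_frames) {
  n_spots <- length(n_fluor)
  surv <- matrix(0L, nrow = n_frames, ncol = n_spots)
  cur <- as.integer(n_fluor)
  for (t in seq_len(n_frames)) {
    surv[t, ] <- cur
    if (bleach_prob > 0 && any(cur > 0))
      cur <- cur - stats::rbinom(n_spots, cur, bleach_prob)
  }
  surv
}

#' Simulate a two-colour single-molecule TIRF movie
#'
#' Renders diffraction-limited emitters with an integrated-Gaussian PSF,
#' per-fluorophore irreversible stochastic photobleaching, Poisson shot
#' noise on signal plus background, and additive Gaussian read noise
#' (clipped at zero and quantized to integer counts, as a camera would).
#' With `noise = FALSE` the analytic expected image is returned instead
#' ("expectation mode"), which is exact and un-quantized.
#'
#' A fraction `colocalized_fraction` of the green spots (each independently)
#' receives a red partner spot displaced by an isotropic Gaussian of
#' standard deviation `coloc_displacement_sigma` pixels; partner identities
#' are recorded in the ground truth.
#'
#' @param config A [sim_config()].
#' @param noise If `FALSE`, skip Poisson/read noise and quantization and
#'   return expected-value frames.
#'
#' @return A list with elements
#'   \describe{
#'     \item{stacks}{named list of [image_stack()] objects, one per channel
#'       present;}
#'     \item{truth}{list with `spots` (data frame: `id`, `x`, `y`,
#'       `n_fluor`, `channel`, `partner` id or `NA`) and `survival`
#'       (frames x spots integer matrix of unbleached fluorophore counts).}
#'   }
#' @export
simulate_tirf_stack <- function(config, noise = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  ss <- config$spot_specs
  if (is.null(ss))
    ss <- data.frame(x = numeric(0), y = numeric(0), n_fluor = integer(0),
                     channel = character(0))
  ss$id <- seq_len(nrow(ss))
  ss$partner <- rep(NA_integer_, nrow(ss))

  # red partners for a random subset of green spots
  g <- which(ss$channel == "green")
  if (length(g) > 0 && config$colocalized_fraction > 0) {
    take <- g[stats::runif(length(g)) < config$colocalized_fraction]
    if (length(take) > 0) {
      px <- ss$x[take] + stats::rnorm(length(take),
                                      sd = config$coloc_displacement_sigma)
      py <- ss$y[take] + stats::rnorm(length(take),
                                      sd = config$coloc_displacement_sigma)
      px <- pmin(pmax(px, 0), config$image_width - 1)
      py <- pmin(pmax(py, 0), config$image_height - 1)
      partners <- data.frame(
        x = px, y = py,
        n_fluor = rep(config$partner_n_fluor, length(take)),
        channel = "red",
        id = nrow(ss) + seq_along(take),
        partner = ss$id[take]
      )
      ss$partner[take] <- partners$id
      ss <- rbind(ss, partners)
    }
  }

  surv <- simulate_survival(ss$n_fluor, config$bleach_prob, config$n_frames)

  channels <- intersect(c("green", "red"), unique(ss$channel))
  if (length(channels) == 0) channels <- "green"
  h <- config$image_height; w <- config$image_width
  stacks <- list()
  for (ch in channels) {
    idx <- which(ss$channel == ch)
    frames <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      expected <- matrix(config$background_rate, nrow = h, ncol = w)
      for (k in idx) {
        if (surv[t, k] > 0)
          expected <- add_spot(expected, ss$x[k], ss$y[k],
                               surv[t, k] * config$photon_scale,
                               config$psf_sigma)
      }
      if (noise) {
        f <- stats::rpois(length(expected), expected)
        if (config$read_noise_sigma > 0)
          f <- f + stats::rnorm(length(f), sd = config$read_noise_sigma)
        f <- round(pmax(f + config$baseline, 0))
        frames[[t]] <- matrix(f, nrow = h, ncol = w)
      } else {
        frames[[t]] <- expected + config$baseline
      }
    }
    stacks[[ch]] <- image_stack(frames, channel = ch,
                                pixel_size = config$pixel_size,
                                frame_interval = config$frame_interval)
  }

  list(stacks = stacks,
       truth = list(spots = ss[, c("id", "x", "y", "n_fluor", "channel",
                                   "partner")],
                    survival = surv))
}

#' Simulate a single photobleaching intensity trace
#'
#' Generates the intensity time series of one spot carrying `n_fluor`
#' fluorophores, each bleaching irreversibly with per-frame probability
#' `bleach_prob` (or at supplied `bleach_frames`), plus additive Gaussian
#' noise.  The true bleach frames are returned so step-detection can be
#' scored against ground truth.
#'
#' @param n_fluor Initial number of fluorophores (>= 0).
#' @param photon_scale Intensity contributed by one fluorophore, in counts.
#' @param bleach_prob Per-fluorophore per-frame bleaching probability.
#'   Ignored when `bleach_frames` is given.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param n_frames Trace length in frames.
#' @param seed Optional integer seed.
#' @param bleach_frames Optional integer vector of forced bleach frames
#'   (0-based); the surviving count drops by one *at* each listed frame,
#'   i.e. the listed frame is the first frame showing the reduced level.
#'
#' @return List with `values` (numeric trace), `true_counts` (surviving
#'   fluorophores per frame) and `bleach_frames` (0-based, sorted).
#' @export
simulate_trace <- function(n_fluor, photon_scale, bleach_prob = 0,
                           noise_sigma = 0, n_frames = 100, seed = NULL,
                           bleach_frames = NULL) {
  stopifnot(n_fluor >= 0, photon_scale > 0, noise_sigma >= 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(bleach_frames)) {
    stopifnot(length(bleach_frames) <= n_fluor)
    counts <- n_fluor - vapply(
      seq_len(n_frames) - 1L,
      function(t) sum(bleach_frames <= t), numeric(1))
    events <- sort(as.integer(bleach_frames))
  } else {
    surv <- simulate_survival(n_fluor, bleach_prob, n_frames)
    counts <- as.numeric(surv[, 1])
    events <- which(diff(c(n_fluor, counts)) < 0) - 1L
    events <- rep(events, times = -diff(c(n_fluor, counts))[events + 1L])
  }
  values <- counts * photon_scale
  if (noise_sigma > 0)
    values <- values + stats::rnorm(n_frames, sd = noise_sigma)
  list(values = values, true_counts = counts, bleach_frames = events)
}

#' Simulate a multi-channel tissue-like image with segmentable nuclei
#'
#' Renders a nuclei channel containing filled discs on a noisy background,
#' plus two signal channels whose per-pixel correlation is controlled by a
#' mixing coefficient: channel A carries a standard-normal field `Z`,
#' channel B carries `alpha * Z + (1 - alpha) * Z'` with `Z'` independent,
#' both on a constant baseline.  The resulting true Pearson correlation is
#' `alpha / sqrt(alpha^2 + (1 - alpha)^2)`, recorded in the ground truth.
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range Length-2 numeric range of disc radii, in pixels.
#' @param alpha Channel-mixing coefficient in `[0, 1]`.
#' @param nucleus_intensity Intensity of nucleus discs above background.
#' @param background Baseline intensity of every channel.
#' @param noise_sd Standard deviation of the signal-channel noise fields and
#'   of the nuclei-channel background noise.
#' @param min_separation Minimum centre-to-centre distance between nuclei;
#'   defaults to twice the maximum radius plus 2 px.  An error is raised if
#'   the requested nuclei cannot be packed.
#' @param seed Integer seed.
#'
#' @return List with `channels` (named list of matrices: `nuclei`, `chA`,
#'   `chB`) and `truth` (data frame of nucleus `id`, `x`, `y`, `radius`,
#'   `area_px`, plus attributes `alpha` and `r_true`).
#' @export
simulate_tissue_image <- function(width = 256, height = 256, n_nuclei = 10,
                                  radius_range = c(6, 12), alpha = 0.5,
                                  nucleus_intensity = 1000, background = 100,
                                  noise_sd = 20, min_separation = NULL,
                                  seed = 1234) {
  stopifnot(alpha >= 0, alpha <= 1, n_nuclei >= 0,
            length(radius_range) == 2, all(radius_range > 0))
  set.seed(seed)
  if (is.null(min_separation)) min_separation <- 2 * max(radius_range) + 2

  # rejection-sample non-overlapping centres
  margin <- ceiling(max(radius_range)) + 1
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0
  while (length(cx) < n_nuclei) {
    tries <- tries + 1
    if (tries > 1000 * max(1, n_nuclei))
      stop("cannot pack ", n_nuclei, " nuclei at min_separation ",
           min_separation, " into a ", width, "x", height, " image")
    px <- stats::runif(1, margin, width - 1 - margin)
    py <- stats::runif(1, margin, height - 1 - margin)
    if (length(cx) == 0 ||
        all((cx - px)^2 + (cy - py)^2 >= min_separation^2)) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  radii <- stats::runif(n_nuclei, radius_range[1], radius_range[2])

  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  nuc <- matrix(0, height, width)
  area <- integer(n_nuclei)
  for (i in seq_len(n_nuclei)) {
    disc <- (xs - cx[i])^2 + (ys - cy[i])^2 <= radii[i]^2
    area[i] <- sum(disc)
    nuc[disc] <- nucleus_intensity
  }
  nuc <- pmax(nuc + background +
                stats::rnorm(length(nuc), sd = noise_sd), 0)
  nuc <- matrix(nuc, height, width)

  z_shared <- matrix(stats::rnorm(height * width), height, width)
  z_indep <- matrix(stats::rnorm(height * width), height, width)
  chA <- background + noise_sd * z_shared
  chB <- background + noise_sd * (alpha * z_shared + (1 - alpha) * z_indep)

  truth <- data.frame(id = seq_len(n_nuclei), x = cx, y = cy,
                      radius = radii, area_px = area)
  attr(truth, "alpha") <- alpha
  attr(truth, "r_true") <- alpha / sqrt(alpha^2 + (1 - alpha)^2)

  list(channels = list(nuclei = nuc, chA = pmax(chA, 0), chB = pmax(chB, 0)),
       truth = truth)
}
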