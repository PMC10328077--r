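# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms/code paths than the package.

# Least-squares fit of an integrated 2-D Gaussian plus flat background to a
# ROI, by Nelder-Mead over (x0, y0, log sigma, log amplitude, background).
# Returns the fitted centre c(x, y) in 0-based ROI coordinates.
fit_gaussian_ls <- function(roi, psf_sigma = 1.3) {
  xs <- 0:(ncol(roi) - 1)
  ys <- 0:(nrow(roi) - 1)
  model <- function(p) {
    px <- pnorm(xs + 0.5, p[1], exp(p[3])) - pnorm(xs - 0.5, p[1], exp(p[3]))
    py <- pnorm(ys + 0.5, p[2], exp(p[3])) - pnorm(ys - 0.5, p[2], exp(p[3]))
    exp(p[4]) * outer(py, px) + p[5]
  }
  obj <- function(p) sum((roi - model(p))^2)
  b0 <- median(roi)
  amp0 <- max(sum(roi - b0), max(roi) - b0)
  start <- c(which.max(apply(roi, 2, max)) - 1,
             which.max(apply(roi, 1, max)) - 1,
             log(psf_sigma), log(max(amp0, 1e-6)), b0)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  fit$par[1:2]
}

# Direct, loop-based evaluation of the Chung-Kennedy filter exactly as
# documented: per point and window, past/future predictor means with
# truncated windows, local mean squared prediction error on the
# predictor's own side, weights (error)^-p normalised, zero-error
# predictors exact and sharing the weight equally.
ck_reference <- function(x, windows, p) {
  n <- length(x)
  if (n == 1) return(x)
  past_mean <- function(t, w) {
    lo <- max(1, t - w); hi <- t - 1
    if (hi < lo) NA_real_ else mean(x[lo:hi])
  }
  fut_mean <- function(t, w) {
    lo <- t + 1; hi <- min(n, t + w)
    if (hi < lo) NA_real_ else mean(x[lo:hi])
  }
  out <- numeric(n)
  for (t in seq_len(n)) {
    mus <- numeric(0); vs <- numeric(0)
    for (w in windows) {
      mp <- past_mean(t, w)
      if (!is.na(mp)) {
        errs <- c()
        for (s in max(1, t - w + 1):t) {
          ms <- past_mean(s, w)
          if (!is.na(ms)) errs <- c(errs, (x[s] - ms)^2)
        }
        v <- if (length(errs) == 0) 0 else sum(errs) / max(length(errs), 1)
        mus <- c(mus, mp); vs <- c(vs, v)
      }
      mf <- fut_mean(t, w)
      if (!is.na(mf)) {
        errs <- c()
        for (s in t:min(n, t + w - 1)) {
          ms <- fut_mean(s, w)
          if (!is.na(ms)) errs <- c(errs, (x[s] - ms)^2)
        }
        v <- if (length(errs) == 0) 0 else sum(errs) / max(length(errs), 1)
        mus <- c(mus, mf); vs <- c(vs, v)
      }
    }
    if (length(mus) == 0) { out[t] <- x[t]; next }
    if (any(vs <= 0)) {
      out[t] <- mean(mus[vs <= 0])
    } else {
      w_ <- vs^(-p)
      out[t] <- sum(w_ * mus) / sum(w_)
    }
  }
  out
}

# Exhaustive maximum-cardinality minimum-cost matching between two point
# sets, enumerating every injective assignment of a-points to b-points.
brute_force_matching <- function(ax, ay, bx, by, radius) {
  na <- length(ax); nb <- length(bx)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  best <- list(n = -1, cost = Inf, pairs = NULL)
  assign_next <- function(i, used, pairs, cost) {
    if (i > na) {
      np <- if (is.null(pairs)) 0 else nrow(pairs)
      if (np > best$n || (np == best$n && cost < best$cost))
        best <<- list(n = np, cost = cost, pairs = pairs)
      return(invisible())
    }
    assign_next(i + 1, used, pairs, cost)
    for (j in seq_len(nb)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        assign_next(i + 1, used, rbind(pairs, c(i, j)), cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  assign_next(1, rep(FALSE, nb), NULL, 0)
  best
}

# Exhaustive Otsu: for each candidate split (upper edge of each histogram
# bin), classify the raw pixel values directly and compute the
# between-class variance w0*w1*(mu0-mu1)^2; return the argmax threshold.
otsu_exhaustive <- function(v, n_bins = 256) {
  v <- as.numeric(v)
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cands <- breaks[2:n_bins]
  bcv <- vapply(cands, function(th) {
    lo <- v[v <= th]; hi <- v[v > th]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cands[which.max(bcv)]
}

# Brute-force 2-D numerical integration (composite Simpson on a square
# grid) of unit-height Gaussian products, for the overlap-integral oracle.
overlap_numeric <- function(d, sa, sb) {
  gauss2 <- function(x, y, x0, s) exp(-((x - x0)^2 + y^2) / (2 * s^2))
  simpson2d <- function(f, lim, n = 240) {
    h <- (lim[2] - lim[1]) / n
    xs <- seq(lim[1], lim[2], length.out = n + 1)
    wx <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    g <- outer(xs, xs, f)
    (h / 3)^2 * as.numeric(t(wx) %*% g %*% wx)
  }
  lim <- c(-8 * max(sa, sb) - abs(d), 8 * max(sa, sb) + abs(d))
  iab <- simpson2d(function(x, y) gauss2(x, y, 0, sa) * gauss2(x, y, d, sb),
                   lim)
  iaa <- simpson2d(function(x, y) gauss2(x, y, 0, sa)^2, lim)
  ibb <- simpson2d(function(x, y) gauss2(x, y, d, sb)^2, lim)
  iab / sqrt(iaa * ibb)
}

# Render a single-spot frame via the package simulator (expectation mode
# or with noise) and return frame plus truth.
single_spot_frame <- function(x, y, n_fluor = 1, size = 25,
                              photon_scale = 5000, background = 0,
                              read_noise = 0, noise = FALSE, seed = 1) {
  cfg <- sim_config(image_width = size, image_height = size, n_frames = 1,
                    photon_scale = photon_scale, bleach_prob = 0,
                    background_rate = background,
                    read_noise_sigma = read_noise,
                    spot_specs = data.frame(x = x, y = y, n_fluor = n_fluor,
                                            channel = "green"),
                    seed = seed)
  simulate_tirf_stack(cfg, noise = noise)$stacks$green$frames[[1]]
}

# Grid of well-separated spot positions with sub-pixel jitter.
spot_grid <- function(nx, ny, spacing = 20, margin = 12, jitter = 0.5,
                      seed = 1) {
  set.seed(seed)
  gx <- rep(margin + spacing * (0:(nx - 1)), times = ny)
  gy <- rep(margin + spacing * (0:(ny - 1)), each = nx)
  data.frame(x = gx + runif(nx * ny, -jitter, jitter),
             y = gy + runif(nx * ny, -jitter, jitter))
}
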