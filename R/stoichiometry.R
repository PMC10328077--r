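#' Chung-Kennedy edge-preserving filter
#'
#' Non-linear filter that smooths noise on intensity plateaus while leaving
#' step edges sharp, used to visualise photobleaching steps.  For each time
#' point and each window length `w`, two predictors are formed: the mean of
#' the `w` points strictly before the point (the "forward" predictor) and
#' the mean of the `w` points strictly after it (the "backward" predictor),
#' with truncated windows at the trace edges.  Each predictor is weighted
#' by its local mean squared prediction error, raised to
#' `-weight_exponent`, the error being averaged over the `w` points on the
#' predictor's own side; weights are normalised to sum to one.  A predictor
#' with zero local error is exact and takes all the weight (ties shared
#' equally), which is what makes noiseless plateaus pass through unchanged.
#'
#' @param values Numeric intensity trace.
#' @param windows Integer vector of window lengths (frames).
#' @param weight_exponent Positive exponent applied to the inverse local
#'   prediction error.
#' @param config Optional [pipeline_config()] supplying `ck_windows` and
#'   `ck_weight_exponent` when `windows`/`weight_exponent` are missing.
#'
#' @return Numeric vector of filtered values, same length as `values`.
#' @export
chung_kennedy_filter <- function(values, windows = NULL,
                                 weight_exponent = NULL, config = NULL) {
  config <- default_config(config)
  if (is.null(windows)) windows <- config$ck_windows
  if (is.null(weight_exponent)) weight_exponent <- config$ck_weight_exponent
  n <- length(values)
  if (n == 0) stop("empty trace")
  if (n == 1) return(values)

  num <- numeric(n)
  den <- numeric(n)
  exact_sum <- numeric(n)   # sum of zero-error predictor means
  exact_n <- integer(n)     # count of zero-error predictors

  csum <- cumsum(values)
  # partial sum csum[hi] - csum[lo - 1] with csum[0] == 0, vectorised
  psum <- function(cs, lo, hi) {
    base <- numeric(length(lo))
    base[lo > 1L] <- cs[lo[lo > 1L] - 1L]
    cs[hi] - base
  }
  win_mean <- function(lo, hi) {  # mean of values[lo..hi], clipped; NA if empty
    lo <- pmax(lo, 1L); hi <- pmin(hi, n)
    len <- hi - lo + 1L
    out <- rep(NA_real_, length(len))
    ok <- len >= 1L
    out[ok] <- psum(csum, lo[ok], hi[ok]) / len[ok]
    out
  }

  t_idx <- seq_len(n)
  for (w in windows) {
    # predictor means: strictly past / strictly future points
    mu_p <- win_mean(t_idx - w, t_idx - 1L)
    mu_f <- win_mean(t_idx + 1L, t_idx + w)
    # squared prediction errors at each point
    e_p <- (values - mu_p)^2
    e_f <- (values - mu_f)^2
    # local mean error: past window for the forward predictor, future
    # window for the backward predictor (truncated, NA-aware)
    cs_p <- cumsum(ifelse(is.na(e_p), 0, e_p))
    cn_p <- cumsum(!is.na(e_p))
    cs_f <- cumsum(ifelse(is.na(e_f), 0, e_f))
    cn_f <- cumsum(!is.na(e_f))
    rng_sum <- function(cs, lo, hi) {
      lo <- pmax(lo, 1L); hi <- pmin(hi, n)
      psum(cs, lo, hi)
    }
    v_p <- rng_sum(cs_p, t_idx - w + 1L, t_idx) /
      pmax(rng_sum(cn_p, t_idx - w + 1L, t_idx), 1L)
    v_f <- rng_sum(cs_f, t_idx, t_idx + w - 1L) /
      pmax(rng_sum(cn_f, t_idx, t_idx + w - 1L), 1L)

    for (side in list(list(mu = mu_p, v = v_p), list(mu = mu_f, v = v_f))) {
      ok <- !is.na(side$mu)
      zero <- ok & side$v <= 0
      pos <- ok & side$v > 0
      exact_sum[zero] <- exact_sum[zero] + side$mu[zero]
      exact_n[zero] <- exact_n[zero] + 1L
      wgt <- side$v[pos]^(-weight_exponent)
      num[pos] <- num[pos] + wgt * side$mu[pos]
      den[pos] <- den[pos] + wgt
    }
  }

  out <- numeric(n)
  has_exact <- exact_n > 0
  out[has_exact] <- exact_sum[has_exact] / exact_n[has_exact]
  rest <- !has_exact & den > 0
  out[rest] <- num[rest] / den[rest]
  none <- !has_exact & den <= 0   # no usable predictor (n == 1 handled above)
  out[none] <- values[none]
  out
}

#' Detect photobleaching steps in a filtered trace
#'
#' Change-points are located by recursive binary segmentation: within each
#' segment, the split maximizing the two-sample Student t statistic between
#' the left and right means is accepted when the statistic exceeds
#' `sensitivity`, and both sides are searched recursively.  A split with
#' zero pooled variance and unequal means is always accepted.  Adjacent
#' segments whose means differ by less than `step_merge_factor` times the
#' pooled within-segment standard deviation are then merged.  Only downward
#' transitions are returned.
#'
#' @param values Numeric (typically Chung-Kennedy filtered) trace.
#' @param sensitivity Minimum absolute t statistic; defaults to
#'   `config$step_sensitivity`.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return Data frame of step events: `frame` (0-based index of the first
#'   frame at the new, lower level) and `size` (intensity loss, positive).
#' @export
detect_steps <- function(values, sensitivity = NULL, config = NULL) {
  config <- default_config(config)
  if (is.null(sensitivity)) sensitivity <- config$step_sensitivity
  n <- length(values)
  min_seg <- config$step_min_segment
  if (n < 2 * min_seg)
    return(data.frame(frame = integer(0), size = numeric(0)))

  cps <- integer(0)  # k: boundary between values[..k] and values[k+1..]
  split_segment <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_seg) return(invisible())
    ks <- (lo + min_seg - 1L):(hi - min_seg)
    best_t <- -Inf; best_k <- NA_integer_
    x <- values[lo:hi]
    cx <- cumsum(x); cx2 <- cumsum(x^2)
    ntot <- len
    for (k in ks) {
      n1 <- k - lo + 1L; n2 <- ntot - n1
      s1 <- cx[n1]; s2 <- cx[ntot] - s1
      m1 <- s1 / n1; m2 <- s2 / n2
      ss1 <- cx2[n1] - n1 * m1^2
      ss2 <- (cx2[ntot] - cx2[n1]) - n2 * m2^2
      sp2 <- (ss1 + ss2) / (ntot - 2L)
      tk <- if (sp2 <= 0) {
        if (m1 != m2) Inf else 0
      } else {
        abs(m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      }
      if (tk > best_t) { best_t <- tk; best_k <- k }
    }
    if (!is.na(best_k) && best_t > sensitivity) {
      cps <<- c(cps, best_k)
      split_segment(lo, best_k)
      split_segment(best_k + 1L, hi)
    }
    invisible()
  }
  split_segment(1L, n)
  cps <- sort(cps)
  if (length(cps) == 0)
    return(data.frame(frame = integer(0), size = numeric(0)))

  # segment means and within-segment noise, then merge small jumps
  repeat {
    bounds <- c(0L, cps, n)
    nseg <- length(bounds) - 1L
    means <- numeric(nseg); vars <- numeric(nseg); lens <- integer(nseg)
    for (i in seq_len(nseg)) {
      seg <- values[(bounds[i] + 1L):bounds[i + 1L]]
      means[i] <- mean(seg)
      lens[i] <- length(seg)
      vars[i] <- if (length(seg) > 1) stats::var(seg) else 0
    }
    pooled_sd <- sqrt(sum(vars * pmax(lens - 1L, 0)) /
                        max(sum(pmax(lens - 1L, 0)), 1L))
    floor_ <- config$step_merge_factor * pooled_sd
    jumps <- abs(diff(means))
    drop <- which(jumps < floor_)
    if (length(drop) == 0 || length(cps) == 0) break
    cps <- cps[-drop[which.min(jumps[drop])]]
    if (length(cps) == 0)
      return(data.frame(frame = integer(0), size = numeric(0)))
  }

  bounds <- c(0L, cps, n)
  nseg <- length(bounds) - 1L
  means <- vapply(seq_len(nseg), function(i)
    mean(values[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  sizes <- means[-nseg] - means[-1]
  down <- sizes > 0
  data.frame(frame = cps[down], size = sizes[down])
}

#' Collect candidate single-fluorophore intensities from tracks
#'
#' Scans every track's (Chung-Kennedy filtered) trace for photobleaching
#' steps and returns the intensities usable for single-dye calibration:
#'
#' * the *terminal plateau* (mean of the trace after its last detected
#'   step, or of the whole trace when it has none) of every track that
#'   terminates before the end of the movie — such tracks end because
#'   their last fluorophore bleached, so their final level is the
#'   brightness of a single dye;
#' * the *final step size* of traces whose last step lands at background
#'   (final plateau below half the step size), i.e. a bleach to zero seen
#'   in full, including single-step traces.
#'
#' @param traces List of traces as returned by [track_traces()].
#' @param n_frames Movie length in frames, used to recognise tracks that
#'   terminate early; `NULL` uses the largest frame index seen plus one.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @return Numeric vector of candidate single-dye intensities.
#' @export
single_dye_intensities <- function(traces, n_frames = NULL, config = NULL) {
  config <- default_config(config)
  if (is.null(n_frames))
    n_frames <- max(vapply(traces, function(tr) max(tr$frames),
                           numeric(1))) + 1
  out <- numeric(0)
  for (tr in traces) {
    if (length(tr$values) < 2 * config$step_min_segment) next
    filt <- chung_kennedy_filter(tr$values, config = config)
    st <- detect_steps(filt, config = config)
    ended_early <- max(tr$frames) < n_frames - 1
    if (nrow(st) == 0) {
      if (ended_early) out <- c(out, mean(filt))
      next
    }
    last <- nrow(st)
    tail_vals <- filt[(st$frame[last] + 1):length(filt)]
    tail_mean <- mean(tail_vals)
    if (abs(tail_mean) < 0.5 * st$size[last]) {
      out <- c(out, st$size[last])           # bleach to background seen
    } else if (ended_early) {
      out <- c(out, tail_mean)               # terminal single-dye plateau
    }
  }
  out
}

#' Characteristic single-fluorophore intensity
#'
#' Summarizes a sample of candidate single-dye intensities into the
#' characteristic intensity used as the stoichiometry denominator.  The
#' default estimator is the mode of a Gaussian kernel density estimate,
#' which is robust to a minority of double-step contaminants; mean and
#' median are available alternatives.
#'
#' @param intensities Numeric vector of candidate single-dye intensities
#'   (step sizes and/or terminal plateau intensities).
#' @param method `"kde_mode"` (default), `"mean"` or `"median"`.
#' @param config Optional [pipeline_config()] supplying the method.
#' @return Scalar characteristic intensity.
#' @export
characteristic_intensity <- function(intensities, method = NULL,
                                     config = NULL) {
  config <- default_config(config)
  if (is.null(method)) method <- config$isingle_method
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) == 0)
    stop("no candidate single-dye intensities; calibrate with ",
         "simulate_trace() or supply traces containing bleaching steps")
  if (length(intensities) < 4 || stats::sd(intensities) == 0)
    return(mean(intensities))
  switch(method,
    kde_mode = {
      d <- stats::density(intensities)
      d$x[which.max(d$y)]
    },
    mean = mean(intensities),
    median = stats::median(intensities)
  )
}

# closed-form OLS of y on x; returns c(intercept, slope)
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

#' Photobleach-corrected stoichiometry of one track
#'
#' Fits an ordinary least-squares line through the first
#' `regression_points` (default 4) raw intensity values of the track
#' against frame number and evaluates it at the track's first frame; this
#' linear extrapolation corrects the initial intensity for bleaching during
#' the first frames and is equivalent, at these short horizons, to a full
#' exponential fit.  The stoichiometry is the corrected initial intensity
#' divided by the characteristic single-fluorophore intensity.
#'
#' Tracks are only eligible when they start within the first
#' `max_start_frame` movie frames (0-based start frame strictly below the
#' threshold); ineligible or too-short tracks are excluded with a reason,
#' not errored.
#'
#' @param values Numeric raw intensity trace of the track.
#' @param start_frame 0-based movie frame of the first trace point.
#' @param i_single Characteristic single-fluorophore intensity (> 0).
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return One-row data frame: `start_frame`, `initial_intensity`,
#'   `i_single`, `stoichiometry`, `excluded` (logical), `reason`.
#' @export
estimate_stoichiometry <- function(values, start_frame, i_single,
                                   config = NULL) {
  config <- default_config(config)
  if (i_single <= 0) stop("i_single must be > 0")
  excluded_row <- function(reason)
    data.frame(start_frame = start_frame, initial_intensity = NA_real_,
               i_single = i_single, stoichiometry = NA_real_,
               excluded = TRUE, reason = reason)
  if (start_frame >= config$max_start_frame)
    return(excluded_row("late_start"))
  k <- config$regression_points
  if (length(values) < k) return(excluded_row("short_track"))
  fit <- ols_fit(0:(k - 1), values[seq_len(k)])
  i0 <- unname(fit["intercept"])
  data.frame(start_frame = start_frame, initial_intensity = i0,
             i_single = i_single, stoichiometry = i0 / i_single,
             excluded = FALSE, reason = "")
}

#' Stoichiometry table for a set of tracks
#'
#' Applies [estimate_stoichiometry()] to every track and attaches the
#' number of detected photobleaching steps per track.
#'
#' @param tracked Data frame from [filter_tracks()].
#' @param i_single Characteristic single-fluorophore intensity; when `NULL`
#'   it is estimated from the tracks via [single_dye_intensities()] and
#'   [characteristic_intensity()].
#' @param n_frames Movie length in frames, forwarded to
#'   [single_dye_intensities()] when calibrating.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return List with `stoichiometry` (one row per track: `track_id`,
#'   `start_frame`, `length`, `initial_intensity`, `i_single`,
#'   `stoichiometry`, `n_steps`, `excluded`, `reason`), `steps` (one row
#'   per step: `track_id`, `frame`, `size`) and `i_single`.
#' @export
stoichiometry_table <- function(tracked, i_single = NULL, n_frames = NULL,
                                config = NULL) {
  config <- default_config(config)
  traces <- track_traces(tracked)
  if (is.null(i_single)) {
    cand <- single_dye_intensities(traces, n_frames, config)
    i_single <- characteristic_intensity(cand, config = config)
  }
  rows <- vector("list", length(traces))
  steps <- vector("list", length(traces))
  ids <- names(traces)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    est <- estimate_stoichiometry(tr$values, tr$frames[1], i_single, config)
    filt <- if (length(tr$values) >= 2 * config$step_min_segment)
      chung_kennedy_filter(tr$values, config = config) else tr$values
    st <- detect_steps(filt, config = config)
    est$track_id <- as.integer(ids[i])
    est$length <- length(tr$values)
    est$n_steps <- nrow(st)
    rows[[i]] <- est
    if (nrow(st) > 0) {
      # step frames are trace-local; shift to movie frames
      st$frame <- st$frame + tr$frames[1]
      st$track_id <- as.integer(ids[i])
      steps[[i]] <- st[, c("track_id", "frame", "size")]
    }
  }
  stoich <- do.call(rbind, rows)
  stoich <- stoich[, c("track_id", "start_frame", "length",
                       "initial_intensity", "i_single", "stoichiometry",
                       "n_steps", "excluded", "reason")]
  rownames(stoich) <- NULL
  steps <- steps[!vapply(steps, is.null, logical(1))]
  steps <- if (length(steps) > 0) do.call(rbind, steps) else
    data.frame(track_id = integer(0), frame = integer(0), size = numeric(0))
  rownames(steps) <- NULL
  list(stoichiometry = stoich, steps = steps, i_single = i_single)
}
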