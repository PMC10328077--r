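# Separable Gaussian blur with edge renormalization, implemented as two
# banded-matrix products so a whole frame is smoothed in two BLAS calls.
gaussian_blur <- function(m, sigma) {
  conv_mat <- function(n) {
    r <- ceiling(3 * sigma)
    k <- stats::dnorm(-r:r, sd = sigma)
    cm <- matrix(0, n, n)
    for (j in seq_len(n)) {
      i <- max(1, j - r):min(n, j + r)
      w <- k[i - j + r + 1]
      cm[i, j] <- w / sum(w)
    }
    cm
  }
  t(conv_mat(nrow(m))) %*% m %*% conv_mat(ncol(m))
}

#' Find candidate spot positions in one frame
#'
#' Smooths the frame with a Gaussian matched approximately to the PSF,
#' estimates the background level (median) and noise (median absolute
#' deviation) of the smoothed frame, and returns the 8-neighbourhood local
#' maxima exceeding `background + candidate_threshold_sigmas * noise`.
#' Maxima closer together than one PSF width (2 * `mask_sigma_px`) are
#' merged, keeping the brighter one; exact ties resolve to the smaller
#' `(y, x)` position.
#'
#' @param frame Numeric matrix (rows = y, columns = x).
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return Data frame of integer seed positions `x`, `y` (0-based) with the
#'   smoothed peak `value`, ordered by decreasing value.
#' @export
find_candidates <- function(frame, config = NULL) {
  config <- default_config(config)
  stopifnot(is.matrix(frame), length(frame) > 0)
  sm <- gaussian_blur(frame, config$mask_sigma_px)
  bg <- stats::median(sm)
  noise <- stats::mad(sm)
  # small epsilon guards against numerical ripple on noiseless frames
  thr <- bg + config$candidate_threshold_sigmas * noise +
    1e-8 * max(abs(bg), 1)

  h <- nrow(sm); w <- ncol(sm)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- sm
  is_max <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (sm >= pad[(2 + dy):(h + 1 + dy),
                                  (2 + dx):(w + 1 + dx)])
  }
  keep <- which(is_max & (sm > thr), arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))
  out <- data.frame(x = keep[, 2] - 1L, y = keep[, 1] - 1L,
                    value = sm[keep])
  out <- out[order(-out$value, out$y, out$x), , drop = FALSE]

  # merge duplicates within one PSF width, brighter first
  merge_r2 <- (2 * config$mask_sigma_px)^2
  taken_x <- numeric(0); taken_y <- numeric(0); sel <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (length(taken_x) == 0 ||
        all((taken_x - out$x[i])^2 + (taken_y - out$y[i])^2 > merge_r2)) {
      sel <- c(sel, i)
      taken_x <- c(taken_x, out$x[i]); taken_y <- c(taken_y, out$y[i])
    }
  }
  rownames(out) <- NULL
  out[sel, , drop = FALSE]
}

# Extract the square ROI centred on an integer position; returns NULL when
# the ROI is not fully supported by the frame (edge spots are excluded).
extract_roi <- function(frame, cx, cy, halfwidth) {
  cx <- as.integer(round(cx)); cy <- as.integer(round(cy))
  if (cx - halfwidth < 0 || cy - halfwidth < 0 ||
      cx + halfwidth > ncol(frame) - 1 || cy + halfwidth > nrow(frame) - 1)
    return(NULL)
  list(values = frame[(cy - halfwidth):(cy + halfwidth) + 1,
                      (cx - halfwidth):(cx + halfwidth) + 1],
       x0 = cx - halfwidth, y0 = cy - halfwidth)
}

roi_border_ring <- function(roi) {
  n <- nrow(roi)
  c(roi[1, ], roi[n, ], roi[2:(n - 1), 1], roi[2:(n - 1), n])
}

#' Refine a spot centroid by iterative Gaussian masking
#'
#' Starting from a seed position, the background-subtracted ROI is
#' repeatedly multiplied by a 2-D Gaussian mask of width `mask_sigma_px`
#' centred on the current estimate and the intensity-weighted centroid of
#' the masked image becomes the new estimate, until the shift falls below
#' `convergence_tol_px` or `max_iterations` is reached.  The local
#' background is the mean of the ROI's 1-px border ring; negative residuals
#' are clamped to zero for the weighting.
#'
#' @param roi Numeric matrix holding the region of interest.
#' @param seed Length-2 numeric `(x, y)` start position in 0-based ROI
#'   coordinates (pixel centres at integers).
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return List with `centroid` `(x, y)` in ROI coordinates, `converged`
#'   (logical: shift criterion met), `iterations`, and `degenerate` (`TRUE`
#'   when the ROI carries no signal above background, in which case the
#'   centroid equals the seed).
#' @export
iterative_gaussian_mask <- function(roi, seed, config = NULL) {
  config <- default_config(config)
  stopifnot(is.matrix(roi), length(seed) == 2)
  if (seed[1] < 0 || seed[1] > ncol(roi) - 1 ||
      seed[2] < 0 || seed[2] > nrow(roi) - 1)
    stop("seed must lie inside the roi")
  b <- mean(roi_border_ring(roi))
  wgt <- pmax(roi - b, 0)
  xs <- 0:(ncol(roi) - 1)
  ys <- 0:(nrow(roi) - 1)
  cur <- as.numeric(seed)
  if (sum(wgt) <= 0)
    return(list(centroid = cur, converged = FALSE, iterations = 0L,
                degenerate = TRUE))
  s <- config$mask_sigma_px
  for (it in seq_len(config$max_iterations)) {
    mask <- outer(exp(-((ys - cur[2])^2) / (2 * s^2)),
                  exp(-((xs - cur[1])^2) / (2 * s^2)))
    mw <- wgt * mask
    tot <- sum(mw)
    if (tot <= 0)
      return(list(centroid = as.numeric(seed), converged = FALSE,
                  iterations = it, degenerate = TRUE))
    nxt <- c(sum(colSums(mw) * xs), sum(rowSums(mw) * ys)) / tot
    shift <- sqrt(sum((nxt - cur)^2))
    cur <- nxt
    if (shift < config$convergence_tol_px)
      return(list(centroid = cur, converged = TRUE, iterations = it,
                  degenerate = FALSE))
  }
  list(centroid = cur, converged = FALSE,
       iterations = config$max_iterations, degenerate = FALSE)
}

#' Measure a focus: background-corrected intensity and SNR
#'
#' Photometry in a square ROI of half-width `roi_halfwidth` centred on the
#' (rounded) centroid.  The local background `b` is the mean of the ROI's
#' 1-px border ring; the summed intensity `I` is the sum of `roi - b` over
#' the inner square (the ROI minus the ring); the signal-to-noise ratio is
#' the mean background-corrected intensity per inner pixel divided by the
#' standard deviation of the border ring.  A zero-variance ring yields the
#' sentinel `snr = Inf` when the focus carries signal and 0 when it does
#' not (so a perfectly flat ROI is still rejected downstream).
#'
#' @param frame Numeric matrix.
#' @param centroid Length-2 numeric `(x, y)`, 0-based frame coordinates.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @param frame_index 0-based frame index stored in the output.
#' @param converged Logical flag propagated from centroid refinement.
#'
#' @return One-row data frame (`frame`, `x`, `y`, `intensity`, `background`,
#'   `snr`, `converged`), or `NULL` for edge spots without full ROI support
#'   and for negative-signal candidates.
#' @export
measure_focus <- function(frame, centroid, config = NULL, frame_index = 0L,
                          converged = TRUE) {
  config <- default_config(config)
  roi <- extract_roi(frame, centroid[1], centroid[2], config$roi_halfwidth)
  if (is.null(roi)) return(NULL)
  v <- roi$values
  ring <- roi_border_ring(v)
  b <- mean(ring)
  inner <- v[2:(nrow(v) - 1), 2:(ncol(v) - 1)]
  intensity <- sum(inner - b)
  if (intensity < 0) return(NULL)
  ring_sd <- stats::sd(ring)
  # zero-variance ring: sentinel Inf when there is signal, 0 otherwise
  snr <- if (ring_sd == 0) {
    if (intensity > 0) Inf else 0
  } else (intensity / length(inner)) / ring_sd
  data.frame(frame = as.integer(frame_index),
             x = centroid[1], y = centroid[2],
             intensity = intensity, background = b, snr = snr,
             converged = converged)
}

#' Accept or reject a focus on its signal-to-noise ratio
#'
#' A focus is accepted only if its SNR is strictly above `snr_min`
#' (default 0.4); a focus at exactly the threshold is rejected.
#'
#' @param focus One-row data frame from [measure_focus()].
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @return Logical.
#' @export
accept_focus <- function(focus, config = NULL) {
  config <- default_config(config)
  focus$snr > config$snr_min
}

#' Detect foci in every frame of a stack
#'
#' Runs candidate finding, iterative Gaussian-mask centroid refinement and
#' photometry on each frame, returning one row per measured focus with its
#' acceptance flag (`snr > snr_min`).
#'
#' @param stack An [image_stack()].
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return Data frame with columns `frame`, `x`, `y`, `intensity`,
#'   `background`, `snr`, `converged`, `accepted`.
#' @export
detect_foci <- function(stack, config = NULL) {
  config <- default_config(config)
  out <- vector("list", length(stack$frames))
  for (t in seq_along(stack$frames)) {
    frame <- stack$frames[[t]]
    cand <- find_candidates(frame, config)
    rows <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      roi <- extract_roi(frame, cand$x[i], cand$y[i], config$roi_halfwidth)
      if (is.null(roi)) next
      fit <- iterative_gaussian_mask(
        roi$values, c(cand$x[i] - roi$x0, cand$y[i] - roi$y0), config)
      if (fit$degenerate) next
      centroid <- fit$centroid + c(roi$x0, roi$y0)
      rows[[i]] <- measure_focus(frame, centroid, config,
                                 frame_index = t - 1L,
                                 converged = fit$converged)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) > 0) out[[t]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0), background = numeric(0),
                      snr = numeric(0), converged = logical(0),
                      accepted = logical(0)))
  foci <- do.call(rbind, out)
  foci$accepted <- foci$snr > config$snr_min
  rownames(foci) <- NULL
  foci
}
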