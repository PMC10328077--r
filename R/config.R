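#' Simulation configuration for synthetic TIRF movies
#'
#' Builds the parameter set describing a simulated two-colour TIRF
#' acquisition.  Defaults reproduce the acquisition geometry the analysis is
#' designed for: 100 nm pixels, 50 ms frame interval, a diffraction-limited
#' point-spread function of about 1.3 px standard deviation, and movies of up
#' to 1,000 frames.
#'
#' All coordinates are 0-based with `x` the column and `y` the row; pixel
#' centers sit at integer coordinates.
#'
#' @param image_width,image_height Image size in pixels.
#' @param n_frames Number of movie frames.
#' @param pixel_size Pixel size in nm (metadata only).
#' @param frame_interval Frame interval in ms (metadata only).
#' @param psf_sigma Standard deviation of the symmetric 2-D Gaussian PSF, in
#'   pixels.  The PSF is integrated over pixel areas, not point-sampled.
#' @param photon_scale Expected photon count emitted per fluorophore per
#'   frame (before bleaching).  The default gives a single fluorophore a
#'   per-pixel signal-to-noise ratio of roughly 5 over the default
#'   background, comparable to a usable single-dye imaging regime.
#' @param bleach_prob Per-fluorophore, per-frame probability of irreversible
#'   photobleaching, in `[0, 1]`.
#' @param background_rate Mean background photon count per pixel per frame.
#' @param read_noise_sigma Standard deviation of additive Gaussian camera
#'   read noise, in counts.
#' @param spot_specs Data frame with one row per emitter: columns `x`, `y`
#'   (sub-pixel position), `n_fluor` (number of fluorophores) and `channel`
#'   (`"green"` or `"red"`).
#' @param colocalized_fraction Fraction of green spots that receive a red
#'   partner spot (each green spot independently with this probability).
#' @param coloc_displacement_sigma Standard deviation, in pixels, of the
#'   isotropic Gaussian displacement between a green spot and its red
#'   partner.
#' @param partner_n_fluor Fluorophore count given to generated red partner
#'   spots.
#' @param baseline Camera baseline offset added to every pixel, in counts.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical simulations.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_tirf_stack()], [simulate_trace()]
#' @export
sim_config <- function(image_width = 64,
                       image_height = 64,
                       n_frames = 100,
                       pixel_size = 100,
                       frame_interval = 50,
                       psf_sigma = 1.3,
                       photon_scale = 4000,
                       bleach_prob = 0.05,
                       background_rate = 20,
                       read_noise_sigma = 2,
                       spot_specs = NULL,
                       colocalized_fraction = 0,
                       coloc_displacement_sigma = 0.3,
                       partner_n_fluor = 1,
                       baseline = 0,
                       seed = 1234) {
  cfg <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    n_frames = as.integer(n_frames),
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    psf_sigma = psf_sigma,
    photon_scale = photon_scale,
    bleach_prob = bleach_prob,
    background_rate = background_rate,
    read_noise_sigma = read_noise_sigma,
    spot_specs = spot_specs,
    colocalized_fraction = colocalized_fraction,
    coloc_displacement_sigma = coloc_displacement_sigma,
    partner_n_fluor = partner_n_fluor,
    baseline = baseline,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$image_width >= 1, cfg$image_height >= 1, cfg$n_frames >= 1,
    cfg$psf_sigma > 0, cfg$photon_scale > 0
  )
  if (cfg$bleach_prob < 0 || cfg$bleach_prob > 1)
    stop("bleach_prob must lie in [0, 1]")
  if (cfg$colocalized_fraction < 0 || cfg$colocalized_fraction > 1)
    stop("colocalized_fraction must lie in [0, 1]")
  if (cfg$background_rate < 0) stop("background_rate must be >= 0")
  if (cfg$read_noise_sigma < 0) stop("read_noise_sigma must be >= 0")
  if (!is.null(cfg$spot_specs)) {
    ss <- cfg$spot_specs
    stopifnot(all(c("x", "y", "n_fluor", "channel") %in% names(ss)))
    if (nrow(ss) > 0) {
      inside <- ss$x >= 0 & ss$x <= cfg$image_width - 1 &
        ss$y >= 0 & ss$y <= cfg$image_height - 1
      if (!all(inside))
        stop("all spot positions must lie inside the image bounds")
      if (any(ss$n_fluor < 0)) stop("n_fluor must be >= 0")
      if (!all(ss$channel %in% c("green", "red")))
        stop("channel must be 'green' or 'red'")
    }
  }
  invisible(cfg)
}

#' Analysis pipeline configuration
#'
#' Collects every tunable threshold of the single-molecule and tissue
#' pipelines.  The five acceptance thresholds keep their conventional strict
#' readings: a focus is kept only if its signal-to-noise ratio is *above*
#' `snr_min`, a track only if it lasts *longer than* `min_track_frames`
#' frames, a focus pair is colocalized only if its overlap integral is *over*
#' `overlap_min`, only tracks starting *within the first*
#' `max_start_frame` movie frames enter stoichiometry estimation, and
#' segmented objects *smaller than* `area_min_px` pixels are discarded.
#'
#' @param snr_min Minimum (exclusive) focus signal-to-noise ratio; default
#'   0.4.  SNR is the mean background-corrected intensity per inner-ROI
#'   pixel divided by the standard deviation of the ROI border ring.
#' @param min_track_frames Minimum (exclusive) track length in frames;
#'   default 3, i.e. tracks of 4 or more foci are kept.
#' @param overlap_min Minimum (exclusive) overlap integral for
#'   colocalization; default 0.75.
#' @param max_start_frame Tracks whose first frame index (0-based) is
#'   `>= max_start_frame` are excluded from stoichiometry; default 10, so
#'   tracks must start within movie frames 0-9.
#' @param regression_points Number of leading trace points used for the
#'   photobleach-correction linear regression; default 4.
#' @param area_min_px Minimum (inclusive) segmented-nucleus area in pixels;
#'   default 50 (objects of 49 px or fewer are removed).
#' @param roi_box_px Side, in pixels, of the square per-cell region of
#'   interest centred on each nucleus centroid; default 100.
#' @param candidate_threshold_sigmas Spot-candidate threshold in robust
#'   standard deviations above the smoothed-frame background.
#' @param link_radius_px Maximum frame-to-frame displacement for track
#'   linking, in pixels.
#' @param mask_sigma_px Standard deviation of the Gaussian mask used for
#'   centroid refinement (and the per-focus width used by the overlap
#'   integral), in pixels.
#' @param convergence_tol_px Centroid shift below which iterative masking
#'   stops, in pixels.
#' @param max_iterations Iteration cap for centroid refinement.
#' @param roi_halfwidth Half-width of the square photometry ROI; the ROI is
#'   `(2 * roi_halfwidth + 1)` pixels on a side.
#' @param ck_windows Chung-Kennedy window lengths, in frames.
#' @param ck_weight_exponent Chung-Kennedy weighting exponent applied to the
#'   inverse local predictor variance.
#' @param step_sensitivity Minimum absolute Welch/Student t statistic for a
#'   candidate photobleaching change-point to be accepted.
#' @param step_min_segment Minimum segment length, in frames, on either side
#'   of a change-point.
#' @param step_merge_factor Adjacent segments whose means differ by less
#'   than `step_merge_factor` times the pooled within-segment standard
#'   deviation are merged.
#' @param isingle_method Estimator of the characteristic single-fluorophore
#'   intensity: mode of a kernel density estimate (default), mean, or
#'   median.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(snr_min = 0.4,
                            min_track_frames = 3,
                            overlap_min = 0.75,
                            max_start_frame = 10,
                            regression_points = 4,
                            area_min_px = 50,
                            roi_box_px = 100,
                            candidate_threshold_sigmas = 5,
                            link_radius_px = 5,
                            mask_sigma_px = 1.3,
                            convergence_tol_px = 0.02,
                            max_iterations = 200,
                            roi_halfwidth = 8,
                            ck_windows = c(2, 4, 8),
                            ck_weight_exponent = 2,
                            step_sensitivity = 5,
                            step_min_segment = 2,
                            step_merge_factor = 2,
                            isingle_method = c("kde_mode", "mean", "median")) {
  cfg <- list(
    snr_min = snr_min,
    min_track_frames = min_track_frames,
    overlap_min = overlap_min,
    max_start_frame = max_start_frame,
    regression_points = regression_points,
    area_min_px = area_min_px,
    roi_box_px = roi_box_px,
    candidate_threshold_sigmas = candidate_threshold_sigmas,
    link_radius_px = link_radius_px,
    mask_sigma_px = mask_sigma_px,
    convergence_tol_px = convergence_tol_px,
    max_iterations = max_iterations,
    roi_halfwidth = roi_halfwidth,
    ck_windows = sort(unique(as.integer(ck_windows))),
    ck_weight_exponent = ck_weight_exponent,
    step_sensitivity = step_sensitivity,
    step_min_segment = as.integer(step_min_segment),
    step_merge_factor = step_merge_factor,
    isingle_method = match.arg(isingle_method)
  )
  stopifnot(
    cfg$snr_min >= 0, cfg$min_track_frames >= 0, cfg$overlap_min >= 0,
    cfg$overlap_min <= 1, cfg$regression_points >= 2,
    cfg$roi_halfwidth >= 2, all(cfg$ck_windows >= 1),
    cfg$step_min_segment >= 1
  )
  class(cfg) <- "pipeline_config"
  cfg
}

default_config <- function(cfg = NULL) {
  if (is.null(cfg)) pipeline_config() else cfg
}
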