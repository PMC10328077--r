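#' Write an image stack to a multi-page TIFF
#'
#' Frames are quantized to 16-bit unsigned integers (counts rounded and
#' clipped to `[0, 65535]`) and written one page per frame, uncompressed.
#' Integer-valued stacks round-trip bit-identically through
#' [read_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$frames, function(f)
    pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Pages are returned in file order as integer count matrices.  Pixel size
#' and frame interval are taken from the arguments (configuration
#' overrides file tags, which are not relied upon).  Mixed page shapes and
#' unreadable files raise errors rather than returning a partial stack.
#'
#' @param path TIFF file path.
#' @param channel Channel label to attach.
#' @param pixel_size Pixel size in nm.
#' @param frame_interval Frame interval in ms.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel = "green", pixel_size = 100,
                       frame_interval = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed frame shapes in ", path)
  image_stack(lapply(pages, function(p) matrix(as.numeric(p), nrow(p))),
              channel = channel, pixel_size = pixel_size,
              frame_interval = frame_interval)
}

write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full single-molecule analysis pipeline
#'
#' Chains every stage on a simulated (or supplied) two-channel acquisition:
#' spot detection, SNR filtering, track linking and duration filtering,
#' Chung-Kennedy filtering and step detection, single-fluorophore
#' calibration, stoichiometry estimation, two-channel colocalization and
#' colocalization-stratified stoichiometry summaries.  All tables, the
#' fully resolved configuration and a plain-text log are written to
#' `out_dir`; re-running with an identical configuration and seed
#' reproduces every output byte for byte.
#'
#' @param sim A [sim_config()] describing the acquisition to simulate, or a
#'   named list of [image_stack()] objects (`green`, optionally `red`) to
#'   analyse directly.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @param out_dir Output directory, created if needed.  `NULL` skips all
#'   file output.
#' @param write_images If `TRUE` (and simulating), the simulated stacks are
#'   also written as multi-page TIFFs.
#'
#' @return Invisibly, a result bundle: `foci`, `tracks` (both per channel),
#'   `stoichiometry`, `steps`, `i_single`, `coloc` (records + proportion),
#'   `stratified`, `truth` (when simulated).
#' @export
run_pipeline <- function(sim, config = NULL, out_dir = NULL,
                         write_images = FALSE) {
  config <- default_config(config)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- NULL
  if (inherits(sim, "sim_config")) {
    note("stage simulate: seed ", sim$seed)
    s <- simulate_tirf_stack(sim)
    stacks <- s$stacks
    truth <- s$truth
  } else {
    stopifnot(is.list(sim), all(vapply(sim, inherits, logical(1),
                                       "image_stack")))
    stacks <- sim
  }

  foci <- list(); tracks <- list()
  for (ch in names(stacks)) {
    note("stage detect [", ch, "]")
    f <- tryCatch(detect_foci(stacks[[ch]], config),
                  error = function(e) stop("stage detect [", ch, "] failed: ",
                                           conditionMessage(e)))
    note("  measured foci: ", nrow(f), ", accepted: ", sum(f$accepted))
    note("stage track [", ch, "]")
    tr <- filter_tracks(link_foci(f, config), config)
    note("  surviving tracks: ",
         if (nrow(tr)) length(unique(tr$track_id)) else 0L)
    f$channel <- ch
    if (nrow(tr)) tr$channel <- ch else tr$channel <- character(0)
    foci[[ch]] <- f
    tracks[[ch]] <- tr
  }

  note("stage stoichiometry [green]")
  green_tracks <- tracks[["green"]]
  stoich <- NULL; steps <- NULL; i_single <- NA_real_
  n_frames <- length(stacks[[1]]$frames)
  if (!is.null(green_tracks) && nrow(green_tracks) > 0) {
    st <- tryCatch(stoichiometry_table(green_tracks, n_frames = n_frames,
                                       config = config),
                   error = function(e) {
                     note("  stoichiometry skipped: ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(st)) {
      stoich <- st$stoichiometry
      steps <- st$steps
      i_single <- st$i_single
      note("  i_single = ", signif(i_single, 6), " counts")
    }
  } else note("  no green tracks")
  if (is.null(stoich))
    stoich <- data.frame(track_id = integer(0), start_frame = integer(0),
                         length = integer(0), initial_intensity = numeric(0),
                         i_single = numeric(0), stoichiometry = numeric(0),
                         n_steps = integer(0), excluded = logical(0),
                         reason = character(0))
  if (is.null(steps))
    steps <- data.frame(track_id = integer(0), frame = integer(0),
                        size = numeric(0))

  note("stage colocalize")
  gsum <- track_summary(if (is.null(green_tracks))
    data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0)) else green_tracks)
  rsum <- track_summary(if (is.null(tracks[["red"]]))
    data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0)) else tracks[["red"]])
  # colocalization uses each track's first detected frame; tracks must
  # start within the same early-frame window as stoichiometry, which keeps
  # late re-detections of bleaching spots out of the denominator
  gsum <- gsum[gsum$start_frame < config$max_start_frame, , drop = FALSE]
  rsum <- rsum[rsum$start_frame < config$max_start_frame, , drop = FALSE]
  gpts <- data.frame(id = gsum$track_id, x = gsum$x0, y = gsum$y0)
  rpts <- data.frame(id = rsum$track_id, x = rsum$x0, y = rsum$y0)
  coloc <- if (nrow(gpts) > 0)
    suppressWarnings(colocalize(gpts, rpts, config))
  else list(records = data.frame(green_id = integer(0), red_id = integer(0),
                                 distance = numeric(0), overlap = numeric(0),
                                 colocalized = logical(0)),
            proportion = 0, n_green = 0L, n_coloc = 0L)
  note("  colocalized ", coloc$n_coloc, " / ", coloc$n_green,
       " green foci (proportion ", signif(coloc$proportion, 4), ")")

  stratified <- if (nrow(stoich) > 0 && nrow(coloc$records) > 0)
    stratify_stoichiometry(stoich, coloc$records) else NULL

  bundle <- list(foci = foci, tracks = tracks, stoichiometry = stoich,
                 steps = steps, i_single = i_single, coloc = coloc,
                 stratified = stratified, truth = truth, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(do.call(rbind, unname(foci)), out_dir, "foci.csv")
    write_table(do.call(rbind, unname(tracks)), out_dir, "tracks.csv")
    write_table(stoich, out_dir, "stoichiometry.csv")
    write_table(steps, out_dir, "steps.csv")
    write_table(coloc$records, out_dir, "colocalization.csv")
    summary_df <- data.frame(n_green = coloc$n_green,
                             n_coloc = coloc$n_coloc,
                             proportion = coloc$proportion,
                             i_single = i_single)
    write_table(summary_df, out_dir, "summary.csv")
    if (!is.null(truth)) write_table(truth$spots, out_dir, "truth_spots.csv")
    cfg_out <- list(pipeline = unclass(config))
    if (inherits(sim, "sim_config"))
      cfg_out$simulation <- unclass(sim)[setdiff(names(sim), "spot_specs")]
    yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
    if (write_images && inherits(sim, "sim_config"))
      for (ch in names(stacks))
        write_stack(stacks[[ch]], file.path(out_dir, paste0(ch, ".tif")))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(bundle)
}
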