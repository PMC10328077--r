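#' Otsu threshold of an image
#'
#' Computes the global threshold maximizing the between-class variance of
#' the intensity histogram (256 bins spanning the data range, by default).
#' Pixels strictly above the threshold are foreground.  The returned value
#' is the upper edge of the chosen background bin, so thresholding with
#' `>` reproduces the optimal histogram split.
#'
#' @param image Numeric matrix (or vector) of intensities with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins over the data range.
#' @return Scalar threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant image: no foreground/background split exists")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  p <- h / sum(h)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)                       # background weight up to bin k
  mu0 <- cumsum(p * centers)            # unnormalised background mean
  mu_t <- mu0[n_bins]
  k <- seq_len(n_bins - 1)              # split after bin k
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  kbest <- which.max(bcv)
  breaks[kbest + 1]                     # upper edge of bin kbest
}

# relabel a labeled matrix so labels are 1..K in raster order of first
# occurrence, after merging diagonal neighbours (8-connectivity)
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)     # 4-connected labels
  nl <- max(lab)
  if (nl == 0) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbour pairs with different non-zero labels
  a <- lab[1:(h - 1), 1:(w - 1)]; b <- lab[2:h, 2:w]
  pairs <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  a <- lab[2:h, 1:(w - 1)]; b <- lab[1:(h - 1), 2:w]
  pairs <- rbind(pairs, cbind(a[a > 0 & b > 0 & a != b],
                              b[a > 0 & b > 0 & a != b]))
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) union_(pairs[r, 1], pairs[r, 2])
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  out
}

#' Clean a binary nuclei mask into labeled nuclei
#'
#' Fills interior holes, labels connected components with 8-connectivity,
#' and removes components smaller than `area_min_px` pixels (strictly: a
#' 49-px object is removed, a 50-px object kept, at the default of 50).
#' Surviving labels are renumbered 1..K.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @return Integer label matrix (0 = background).
#' @export
clean_mask <- function(mask, config = NULL) {
  config <- default_config(config)
  m <- (mask > 0) * 1
  filled <- EBImage::fillHull(m)
  lab <- label_components_8(filled)
  nl <- max(lab)
  if (nl == 0) return(matrix(0L, nrow(m), ncol(m)))
  areas <- tabulate(lab[lab > 0], nbins = nl)
  keep <- which(areas >= config$area_min_px)
  out <- matrix(0L, nrow(m), ncol(m))
  if (length(keep) > 0)
    out[lab %in% keep] <- match(lab[lab %in% keep], keep)
  out
}

#' Per-nucleus square regions of interest
#'
#' Draws a `roi_box_px` x `roi_box_px` (default 100 x 100) box centred on
#' each labeled nucleus centroid, clipped at the image borders (so edge
#' boxes may be smaller).  Box coordinates are 0-based, half-open.
#'
#' @param labels Integer label matrix from [clean_mask()].
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @return Data frame: `label`, `area`, `x`, `y` (centroid, 0-based),
#'   `row0`, `col0`, `height`, `width`.
#' @export
cell_rois <- function(labels, config = NULL) {
  config <- default_config(config)
  nl <- max(labels)
  h <- nrow(labels); w <- ncol(labels)
  box <- config$roi_box_px
  half_lo <- floor((box - 1) / 2)       # pixels before the centre pixel
  out <- vector("list", nl)
  for (l in seq_len(nl)) {
    px <- which(labels == l, arr.ind = TRUE)
    cy <- mean(px[, 1] - 1); cx <- mean(px[, 2] - 1)
    r0 <- round(cy) - half_lo; c0 <- round(cx) - half_lo
    r1 <- r0 + box; c1 <- c0 + box      # half-open upper bounds
    r0 <- max(r0, 0); c0 <- max(c0, 0)
    r1 <- min(r1, h); c1 <- min(c1, w)
    out[[l]] <- data.frame(label = l, area = nrow(px), x = cx, y = cy,
                           row0 = r0, col0 = c0,
                           height = r1 - r0, width = c1 - c0)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(label = integer(0), area = integer(0), x = numeric(0),
                      y = numeric(0), row0 = integer(0), col0 = integer(0),
                      height = integer(0), width = integer(0))
  res
}

extract_box <- function(image, roi) {
  image[(roi$row0 + 1):(roi$row0 + roi$height),
        (roi$col0 + 1):(roi$col0 + roi$width), drop = FALSE]
}

#' Pearson correlation between two channel ROIs
#'
#' Correlation over all pixels of two equal-shaped regions of interest.
#' When either channel has zero variance in the ROI the correlation is
#' undefined and `NA` is returned with a warning stating the reason.
#'
#' @param roi_a,roi_b Equal-shaped numeric matrices (or vectors) with at
#'   least two pixels.
#' @return Pearson correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
roi_channel_correlation <- function(roi_a, roi_b) {
  a <- as.numeric(roi_a); b <- as.numeric(roi_b)
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in one channel: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Background level of a channel via the histogram mode
#'
#' The per-image background used for summed-intensity correction: the
#' centre of the most populated intensity histogram bin.
#'
#' @param image Numeric matrix.
#' @param n_bins Number of histogram bins over the data range.
#' @return Scalar background estimate.
#' @export
channel_background <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  centers[which.max(h)]
}

#' Summed background-corrected ROI intensity
#'
#' Sum over the ROI of the pixel intensities above background, with
#' negative residuals clipped to zero.
#'
#' @param roi Numeric matrix or vector of ROI pixels.
#' @param background Scalar background level (e.g. [channel_background()]).
#' @return Scalar summed corrected intensity.
#' @export
roi_summed_intensity <- function(roi, background) {
  stopifnot(length(roi) > 0)
  sum(pmax(as.numeric(roi) - background, 0))
}

#' Per-cell colocalization analysis of a multi-channel tissue image
#'
#' Segments the nuclei channel with Otsu's method, cleans the mask (hole
#' filling, 8-connected labeling, minimum-area filter), draws a square ROI
#' around each nucleus centroid, and reports for every cell the Pearson
#' correlation between each declared channel pair over the ROI and the
#' summed background-corrected intensity of each channel (background =
#' per-channel histogram mode).
#'
#' @param channels Named list of equal-sized numeric matrices.
#' @param nuclei_channel Name (or index) of the nuclei channel.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return Data frame with one row per nucleus: `label`, `area`, `x`, `y`,
#'   one `r_<a>_<b>` column per channel pair and one `sum_<ch>` column per
#'   non-nuclei channel.
#' @export
analyze_tissue <- function(channels, nuclei_channel = "nuclei",
                           config = NULL) {
  config <- default_config(config)
  stopifnot(is.list(channels), length(channels) >= 2)
  nuc <- channels[[nuclei_channel]]
  thr <- otsu_threshold(nuc)
  labels <- clean_mask(nuc > thr, config)
  rois <- cell_rois(labels, config)
  sig_names <- setdiff(names(channels),
                       if (is.character(nuclei_channel)) nuclei_channel
                       else names(channels)[nuclei_channel])
  bg <- vapply(sig_names, function(ch) channel_background(channels[[ch]]),
               numeric(1))
  pairs <- if (length(sig_names) >= 2) utils::combn(sig_names, 2) else NULL
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    if (!is.null(pairs)) {
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1, p]; b <- pairs[2, p]
        r <- suppressWarnings(roi_channel_correlation(
          extract_box(channels[[a]], roi), extract_box(channels[[b]], roi)))
        rois[i, paste0("r_", a, "_", b)] <- r
      }
    }
    for (ch in sig_names)
      rois[i, paste0("sum_", ch)] <- roi_summed_intensity(
        extract_box(channels[[ch]], roi), bg[[ch]])
  }
  rois
}
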