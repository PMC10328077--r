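#' Overlap integral between two Gaussian foci
#'
#' Models each focus as a unit-height symmetric 2-D Gaussian and computes
#' the normalised cross-correlation
#' \deqn{O = \frac{\int G_A G_B \, dx\,dy}
#'               {\sqrt{\int G_A^2 \int G_B^2}}
#'         = \frac{2\sigma_A\sigma_B}{\sigma_A^2+\sigma_B^2}
#'           \exp\!\left(-\frac{d^2}{2(\sigma_A^2+\sigma_B^2)}\right),}
#' a dimensionless quantity in `[0, 1]` that equals 1 for identical foci
#' and decays monotonically with the centre distance `d`.  This closed form
#' is the analytic value of the two Gaussian integrals; it reduces the
#' colocalization criterion `O > 0.75` to an interpretable distance test.
#'
#' @param d Centre-to-centre distance in pixels (vectorised).
#' @param sigma_a,sigma_b Gaussian widths of the two foci, in pixels (> 0).
#' @return Overlap integral(s) in `[0, 1]`.
#' @export
overlap_integral <- function(d, sigma_a, sigma_b = sigma_a) {
  if (any(sigma_a <= 0) || any(sigma_b <= 0))
    stop("sigma_a and sigma_b must be > 0")
  s2 <- sigma_a^2 + sigma_b^2
  (2 * sigma_a * sigma_b / s2) * exp(-d^2 / (2 * s2))
}

#' Pair green and red foci by overlap integral
#'
#' Candidate pairs are all green/red combinations whose centre distance is
#' within `3 * sqrt(sigma_a^2 + sigma_b^2)`; they are assigned one-to-one
#' greedily by descending overlap integral (each focus used at most once).
#' A pair is flagged colocalized only when its overlap integral is strictly
#' above `overlap_min` (default 0.75).  The per-field proportion is the
#' number of colocalized green foci over all green foci.
#'
#' @param green,red Data frames with columns `x`, `y` and optionally an
#'   `id`/`track_id` column (first-frame positions of each focus or track).
#' @param config A [pipeline_config()]; `NULL` uses defaults.  The focus
#'   width used for the overlap integral is `mask_sigma_px` for both
#'   channels.
#' @param sigma_green,sigma_red Optional per-channel Gaussian widths
#'   overriding the config.
#'
#' @return List with `records` (one row per green focus: `green_id`,
#'   `red_id` or `NA`, `distance`, `overlap`, `colocalized`), `proportion`,
#'   `n_green`, `n_coloc`.
#' @export
colocalize <- function(green, red, config = NULL, sigma_green = NULL,
                       sigma_red = NULL) {
  config <- default_config(config)
  if (is.null(sigma_green)) sigma_green <- config$mask_sigma_px
  if (is.null(sigma_red)) sigma_red <- config$mask_sigma_px
  id_of <- function(df) {
    if ("id" %in% names(df)) df$id
    else if ("track_id" %in% names(df)) df$track_id
    else seq_len(nrow(df))
  }
  gid <- id_of(green); rid <- id_of(red)
  ng <- nrow(green)
  if (ng == 0) {
    warning("no green foci; proportion set to 0")
    return(list(records = data.frame(green_id = integer(0),
                                     red_id = integer(0),
                                     distance = numeric(0),
                                     overlap = numeric(0),
                                     colocalized = logical(0)),
                proportion = 0, n_green = 0L, n_coloc = 0L))
  }
  records <- data.frame(green_id = gid, red_id = NA_integer_,
                        distance = NA_real_, overlap = NA_real_,
                        colocalized = FALSE)
  if (nrow(red) == 0) {
    warning("no red foci; proportion set to 0")
    return(list(records = records, proportion = 0, n_green = ng,
                n_coloc = 0L))
  }
  d <- sqrt(outer(green$x, red$x, "-")^2 + outer(green$y, red$y, "-")^2)
  reach <- 3 * sqrt(sigma_green^2 + sigma_red^2)
  cand <- which(d <= reach, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    o <- overlap_integral(d[cand], sigma_green, sigma_red)
    ord <- order(-o, d[cand])
    used_g <- rep(FALSE, ng); used_r <- rep(FALSE, nrow(red))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_g[i] || used_r[j]) next
      used_g[i] <- TRUE; used_r[j] <- TRUE
      records$red_id[i] <- rid[j]
      records$distance[i] <- d[i, j]
      records$overlap[i] <- o[k]
      records$colocalized[i] <- o[k] > config$overlap_min
    }
  }
  n_coloc <- sum(records$colocalized)
  list(records = records, proportion = n_coloc / ng, n_green = ng,
       n_coloc = n_coloc)
}

#' Stoichiometry stratified by colocalization status
#'
#' Splits track stoichiometries by whether the track's focus is colocalized
#' with the other channel and summarizes each group (n, median, quartiles,
#' mean).  Group means are compared with a two-sided two-sample Student
#' t-test (equal variances).  When both groups have zero variance the test
#' is degenerate: the comparison is flagged and reported as p = 1 for equal
#' means or p = 0 (maximally significant) otherwise.
#'
#' @param stoich Data frame from [stoichiometry_table()] (`track_id`,
#'   `stoichiometry`).
#' @param records Colocalization records from [colocalize()] (`green_id`,
#'   `colocalized`).
#'
#' @return List with `summary` (one row per group), `t_statistic`,
#'   `p_value`, `degenerate` and `note`.
#' @export
stratify_stoichiometry <- function(stoich, records) {
  m <- merge(stoich, records[, c("green_id", "colocalized")],
             by.x = "track_id", by.y = "green_id")
  m <- m[!is.na(m$stoichiometry), , drop = FALSE]
  grp <- split(m$stoichiometry, m$colocalized)
  summ <- do.call(rbind, lapply(names(grp), function(g) {
    s <- grp[[g]]
    data.frame(colocalized = as.logical(g), n = length(s),
               median = stats::median(s),
               q25 = unname(stats::quantile(s, 0.25)),
               q75 = unname(stats::quantile(s, 0.75)),
               mean = mean(s))
  }))
  res <- list(summary = summ, t_statistic = NA_real_, p_value = NA_real_,
              degenerate = FALSE, note = "")
  if (length(grp) < 2 || any(vapply(grp, length, integer(1)) < 2)) {
    res$note <- "group with n < 2: test not performed"
    return(res)
  }
  a <- grp[[1]]; b <- grp[[2]]
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    res$degenerate <- TRUE
    if (mean(a) == mean(b)) {
      res$t_statistic <- 0; res$p_value <- 1
    } else {
      res$t_statistic <- Inf * sign(mean(a) - mean(b)); res$p_value <- 0
      res$note <- "zero variance in both groups with unequal means"
    }
    return(res)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  res$t_statistic <- unname(tt$statistic)
  res$p_value <- tt$p.value
  res
}
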