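# Minimum-cost maximum-cardinality assignment between two point sets,
# restricted to pairs within `radius`.  The candidate graph is split into
# connected components; each small component is solved exactly by
# enumeration (maximize matched pairs, then minimize total displacement);
# oversized components fall back to greedy nearest-pair assignment.
match_points <- function(ax, ay, bx, by, radius, max_exact = 8L) {
  na <- length(ax); nb <- length(bx)
  if (na == 0 || nb == 0)
    return(data.frame(a = integer(0), b = integer(0)))
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  cand <- d <= radius
  if (!any(cand)) return(data.frame(a = integer(0), b = integer(0)))

  # connected components over the bipartite candidate graph
  comp_a <- rep(0L, na); comp_b <- rep(0L, nb); nc <- 0L
  for (i in seq_len(na)) {
    if (comp_a[i] != 0L || !any(cand[i, ])) next
    nc <- nc + 1L
    qa <- i
    while (length(qa) > 0) {
      comp_a[qa] <- nc
      qb <- which(apply(cand[qa, , drop = FALSE], 2, any) & comp_b == 0L)
      if (length(qb) == 0) break
      comp_b[qb] <- nc
      qa <- which(apply(cand[, qb, drop = FALSE], 1, any) & comp_a == 0L)
    }
  }

  res_a <- integer(0); res_b <- integer(0)
  for (k in seq_len(nc)) {
    ia <- which(comp_a == k); ib <- which(comp_b == k)
    if (length(ia) == 1 && length(ib) == 1) {
      res_a <- c(res_a, ia); res_b <- c(res_b, ib)
      next
    }
    if (length(ia) + length(ib) <= max_exact) {
      sol <- exact_assignment(d[ia, ib, drop = FALSE],
                              cand[ia, ib, drop = FALSE])
      res_a <- c(res_a, ia[sol$a]); res_b <- c(res_b, ib[sol$b])
    } else {
      sol <- greedy_assignment(d[ia, ib, drop = FALSE],
                               cand[ia, ib, drop = FALSE])
      res_a <- c(res_a, ia[sol$a]); res_b <- c(res_b, ib[sol$b])
    }
  }
  data.frame(a = res_a, b = res_b)
}

# exhaustive search: maximum number of matches, ties broken by minimum
# total displacement
exact_assignment <- function(d, cand) {
  na <- nrow(d)
  best <- list(n = -1L, cost = Inf, a = integer(0), b = integer(0))
  recurse <- function(i, used_b, a_sel, b_sel, cost) {
    if (i > na) {
      n <- length(a_sel)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, a = a_sel, b = b_sel)
      return(invisible())
    }
    # upper bound prune: even matching all remaining rows can't beat best
    if (length(a_sel) + (na - i + 1L) < best$n) return(invisible())
    recurse(i + 1L, used_b, a_sel, b_sel, cost)  # leave row i unmatched
    for (j in which(cand[i, ] & !used_b)) {
      used_b[j] <- TRUE
      recurse(i + 1L, used_b, c(a_sel, i), c(b_sel, j), cost + d[i, j])
      used_b[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ncol(d)), integer(0), integer(0), 0)
  best
}

greedy_assignment <- function(d, cand) {
  dd <- d; dd[!cand] <- Inf
  a <- integer(0); b <- integer(0)
  while (any(is.finite(dd))) {
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- c(a, ij[1]); b <- c(b, ij[2])
    dd[ij[1], ] <- Inf; dd[, ij[2]] <- Inf
  }
  list(a = a, b = b)
}

#' Link accepted foci across frames into tracks
#'
#' Performs frame-to-frame nearest-neighbour linking: foci in frame *t + 1*
#' within `link_radius_px` of a track head in frame *t* are candidate
#' continuations, and each frame pair is resolved globally by the
#' assignment maximizing the number of links and, among those, minimizing
#' the total displacement.  Unmatched foci start new tracks; an unmatched
#' track head terminates its track (no gap closing, so a missed detection
#' ends a track).
#'
#' Only rows with `accepted == TRUE` are linked when the column is present.
#'
#' @param foci Data frame from [detect_foci()] (columns `frame`, `x`, `y`,
#'   `intensity`, ...).
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#'
#' @return The accepted foci with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_foci <- function(foci, config = NULL) {
  config <- default_config(config)
  if ("accepted" %in% names(foci)) foci <- foci[foci$accepted, , drop = FALSE]
  foci <- foci[order(foci$frame, foci$y, foci$x), , drop = FALSE]
  rownames(foci) <- NULL
  n <- nrow(foci)
  if (n == 0) {
    foci$track_id <- integer(0)
    return(foci)
  }
  track_id <- rep(NA_integer_, n)
  frames <- sort(unique(foci$frame))
  next_id <- 0L
  prev_idx <- integer(0)  # row indices of current track heads
  prev_frame <- -Inf
  for (f in frames) {
    cur_idx <- which(foci$frame == f)
    if (length(prev_idx) > 0 && f == prev_frame + 1) {
      m <- match_points(foci$x[prev_idx], foci$y[prev_idx],
                        foci$x[cur_idx], foci$y[cur_idx],
                        config$link_radius_px)
      track_id[cur_idx[m$b]] <- track_id[prev_idx[m$a]]
    }
    new <- cur_idx[is.na(track_id[cur_idx])]
    if (length(new) > 0) {
      track_id[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  foci$track_id <- track_id
  foci <- foci[order(foci$track_id, foci$frame), , drop = FALSE]
  rownames(foci) <- NULL
  foci
}

#' Remove tracks that do not last longer than the minimum duration
#'
#' Keeps a track only if its length `L` (number of linked foci) is strictly
#' greater than `min_track_frames` (default 3): a track of exactly 3 frames
#' is removed, one of 4 is kept.
#'
#' @param tracked Data frame from [link_foci()] with a `track_id` column.
#' @param config A [pipeline_config()]; `NULL` uses defaults.
#' @return The surviving rows of `tracked`.
#' @export
filter_tracks <- function(tracked, config = NULL) {
  config <- default_config(config)
  if (nrow(tracked) == 0) return(tracked)
  len <- table(tracked$track_id)
  keep <- names(len)[len > config$min_track_frames]
  out <- tracked[tracked$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize tracks
#'
#' @param tracked Data frame with a `track_id` column.
#' @return One row per track: `track_id`, `start_frame`, `length`, mean
#'   position, and first-frame position `x0`, `y0` (used for
#'   colocalization, which is computed on each track's first detected
#'   frame).
#' @export
track_summary <- function(tracked) {
  if (nrow(tracked) == 0)
    return(data.frame(track_id = integer(0), start_frame = integer(0),
                      length = integer(0), x = numeric(0), y = numeric(0),
                      x0 = numeric(0), y0 = numeric(0)))
  sp <- split(seq_len(nrow(tracked)), tracked$track_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    i <- i[order(tracked$frame[i])]
    data.frame(track_id = tracked$track_id[i[1]],
               start_frame = tracked$frame[i[1]],
               length = length(i),
               x = mean(tracked$x[i]), y = mean(tracked$y[i]),
               x0 = tracked$x[i[1]], y0 = tracked$y[i[1]])
  }))
  rownames(out) <- NULL
  out
}

#' Extract per-track intensity traces
#'
#' @param tracked Data frame with `track_id`, `frame`, `intensity`.
#' @return Named list (by track id) of lists with `frames` (0-based) and
#'   `values`.
#' @export
track_traces <- function(tracked) {
  sp <- split(seq_len(nrow(tracked)), tracked$track_id)
  lapply(sp, function(i) {
    i <- i[order(tracked$frame[i])]
    list(frames = tracked$frame[i], values = tracked$intensity[i])
  })
}
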