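#' @name tracking
#' @title Nearest-neighbor track linking
#'
#' @description
#' Localizations are linked frame by frame into trajectories. For every
#' frame, the eligible open track ends and the frame's localizations are
#' paired by a minimum-total-distance one-to-one assignment restricted to
#' pairs within the linking radius (an optimal assignment, not greedy
#' matching, so the result is order-independent and matches a brute-force
#' oracle). A track end that finds no partner stays open for up to
#' `max_gap` frames — re-appearing (blinking) emitters are bridged with a
#' search radius growing like `sqrt(gap)`, the diffusive scaling — before
#' it closes. Tracks shorter than `min_length` points are discarded.
NULL

# minimum-total-distance maximum-cardinality one-to-one assignment.
# `d` is the n1 x n2 distance matrix; `allowed` a logical matrix of
# admissible pairs. Returns an integer vector of length n1: the matched
# column per row, NA when unmatched. Cardinality dominates cost via a
# weight offset large enough that any extra match outweighs all distances.
solve_assignment <- function(d, allowed) {
  n1 <- nrow(d); n2 <- ncol(d)
  out <- rep(NA_integer_, n1)
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  dmax <- max(d[allowed])
  big <- (min(n1, n2) + 2) * (dmax + 1)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n1), rep(TRUE, n2)),
    edges = as.vector(t(cbind(idx[, 1L], n1 + idx[, 2L])))
  )
  m <- igraph::max_bipartite_match(
    g, weights = big - d[allowed]
  )$matching
  for (i in seq_len(n1)) {
    if (!is.na(m[i])) out[i] <- as.integer(m[i]) - n1
  }
  out
}

#' Link localizations into tracks
#'
#' @param locs localization table (data frame with at least `frame`, `x`,
#'   `y`; typically a refinement [result_table()]).
#' @param max_dist maximum linking distance per frame step, in px (> 0).
#'   Across a bridged gap of `g` frames the radius is
#'   `max_dist * sqrt(g)`.
#' @param max_gap maximum number of consecutive frames a track survives
#'   without a localization (0 = no gap closing).
#' @param min_length minimum number of points for a track to be kept.
#' @return A tracking [result_table()] with columns `track_id`, `frame`,
#'   `x`, `y`, `loc_row` (1-based row of `locs` the point came from) and
#'   `n_gaps` (gaps bridged up to that point), sorted by
#'   `(track_id, frame)`. Track ids are assigned in order of track start
#'   `(frame, y, x)`, starting at 1.
#' @export
link_nearest_neighbor <- function(locs, max_dist, max_gap = 0L, min_length = 1L) {
  stopifnot(max_dist > 0, max_gap >= 0, min_length >= 1)
  locs <- tibble::as_tibble(locs)
  if (nrow(locs) == 0L) return(empty_stage_table("tracking"))

  ord <- order(locs$frame, locs$y, locs$x)
  fr <- as.integer(locs$frame[ord])
  px <- locs$x[ord]; py <- locs$y[ord]
  src <- seq_len(nrow(locs))[ord]

  # open track state, grown as flat vectors for speed
  t_last_f <- integer(0); t_last_x <- numeric(0); t_last_y <- numeric(0)
  t_id <- integer(0)
  n_tracks <- 0L
  start_key <- list(frame = integer(0), y = numeric(0), x = numeric(0))
  pts_track <- integer(length(fr))   # internal track id per localization
  pts_gap <- integer(length(fr))     # gap bridged into this point

  frames <- sort(unique(fr))
  for (f in frames) {
    cur <- which(fr == f)
    # retire tracks that can no longer be reached from frame f onward
    live <- which(f - t_last_f <= max_gap + 1L)
    matched_col <- rep(NA_integer_, length(live))
    if (length(live) > 0L && length(cur) > 0L) {
      gaps <- f - t_last_f[live]
      dx <- outer(t_last_x[live], px[cur], `-`)
      dy <- outer(t_last_y[live], py[cur], `-`)
      d <- sqrt(dx^2 + dy^2)
      radius <- max_dist * sqrt(gaps)
      allowed <- d <= matrix(radius, length(live), length(cur))
      if (any(allowed)) matched_col <- solve_assignment(d, allowed)
    }
    used <- rep(FALSE, length(cur))
    if (length(live) > 0L) {
      for (k in seq_along(live)) {
        j <- matched_col[k]
        if (!is.na(j)) {
          tr <- live[k]
          i <- cur[j]
          pts_track[i] <- t_id[tr]
          pts_gap[i] <- (f - t_last_f[tr]) - 1L
          t_last_f[tr] <- f; t_last_x[tr] <- px[i]; t_last_y[tr] <- py[i]
          used[j] <- TRUE
        }
      }
    }
    # unmatched localizations open new tracks
    for (j in which(!used)) {
      i <- cur[j]
      n_tracks <- n_tracks + 1L
      t_id <- c(t_id, n_tracks)
      t_last_f <- c(t_last_f, f)
      t_last_x <- c(t_last_x, px[i])
      t_last_y <- c(t_last_y, py[i])
      start_key$frame <- c(start_key$frame, f)
      start_key$y <- c(start_key$y, py[i])
      start_key$x <- c(start_key$x, px[i])
      pts_track[i] <- n_tracks
      pts_gap[i] <- 0L
    }
    # keep only still-reachable tracks in the working set
    keep <- which(f - t_last_f <= max_gap + 1L)
    t_id <- t_id[keep]; t_last_f <- t_last_f[keep]
    t_last_x <- t_last_x[keep]; t_last_y <- t_last_y[keep]
  }

  len <- tabulate(pts_track, nbins = n_tracks)
  kept <- which(len >= min_length)
  if (length(kept) == 0L) return(empty_stage_table("tracking"))
  # renumber kept tracks by start (frame, y, x)
  kord <- kept[order(start_key$frame[kept], start_key$y[kept], start_key$x[kept])]
  new_id <- rep(NA_integer_, n_tracks)
  new_id[kord] <- seq_along(kord)

  sel <- which(!is.na(new_id[pts_track]))
  out <- tibble::tibble(
    track_id = as.numeric(new_id[pts_track[sel]]),
    frame = as.numeric(fr[sel]),
    x = px[sel], y = py[sel],
    loc_row = as.numeric(src[sel]),
    n_gaps = as.numeric(pts_gap[sel])
  )
  sort_stage_table(result_table(out, "tracking"), "tracking")
}
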