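# Independent brute-force oracles and small fixtures shared by the tests.

# Exhaustive optimal partial assignment: maximize the number of matched
# pairs, then minimize total distance, by recursion over rows with each
# row either unmatched or matched to any free admissible column.
oracle_assignment <- function(d, allowed) {
  n1 <- nrow(d); n2 <- ncol(d)
  best <- list(n = -1L, cost = Inf, match = rep(NA_integer_, n1))
  used <- rep(FALSE, n2)
  match <- rep(NA_integer_, n1)
  recurse <- function(i, n, cost) {
    if (i > n1) {
      if (n > best$n || (n == best$n && cost < best$cost - 1e-12)) {
        best <<- list(n = n, cost = cost, match = match)
      }
      return(invisible(NULL))
    }
    for (j in seq_len(n2)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <<- TRUE; match[i] <<- j
        recurse(i + 1L, n + 1L, cost + d[i, j])
        used[j] <<- FALSE; match[i] <<- NA_integer_
      }
    }
    recurse(i + 1L, n, cost)
  }
  recurse(1L, 0L, 0)
  best
}

# frame-sweep linker identical in policy to link_nearest_neighbor but with
# the exhaustive assignment above (no gap closing)
oracle_link <- function(locs, max_dist) {
  locs <- locs[order(locs$frame, locs$y, locs$x), ]
  frames <- sort(unique(locs$frame))
  track_of <- rep(NA_integer_, nrow(locs))
  open_rows <- integer(0)   # row index of each open track's last point
  next_id <- 0L
  for (f in frames) {
    cur <- which(locs$frame == f)
    live <- open_rows[locs$frame[open_rows] == f - 1]
    assigned <- rep(FALSE, length(cur))
    if (length(live) > 0L && length(cur) > 0L) {
      d <- sqrt(outer(locs$x[live], locs$x[cur], `-`)^2 +
                  outer(locs$y[live], locs$y[cur], `-`)^2)
      m <- oracle_assignment(d, d <= max_dist)$match
      for (k in seq_along(live)) {
        if (!is.na(m[k])) {
          i <- cur[m[k]]
          track_of[i] <- track_of[live[k]]
          open_rows[open_rows == live[k]] <- i
          assigned[m[k]] <- TRUE
        }
      }
    }
    for (j in which(!assigned)) {
      next_id <- next_id + 1L
      track_of[cur[j]] <- next_id
      open_rows <- c(open_rows, cur[j])
    }
  }
  tibble::tibble(row = seq_len(nrow(locs)), frame = locs$frame,
                 x = locs$x, y = locs$y, track = track_of)
}

# canonical multiset of per-track point sequences, for comparing linkers
# independent of track numbering
track_signature <- function(frame, x, y, id) {
  sigs <- vapply(split(paste(frame, round(x, 9), round(y, 9)), id),
                 function(s) paste(sort(s), collapse = ";"), character(1))
  sort(unname(sigs))
}

# dense midpoint quadrature of the 2D Gaussian over one pixel, as an
# erf-free oracle for the pixel-integrated PSF model
quadrature_pixel_gaussian <- function(cx, cy, mu_x, mu_y, sigma, n_sub = 41L) {
  xs <- cx + (seq_len(n_sub) - (n_sub + 1) / 2) / n_sub
  ys <- cy + (seq_len(n_sub) - (n_sub + 1) / 2) / n_sub
  gx <- exp(-(xs - mu_x)^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  gy <- exp(-(ys - mu_y)^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  sum(outer(gy, gx)) / n_sub^2
}

# noiseless rendered spot window used across refinement tests
render_spot_window <- function(n = 15, mu_x, mu_y, N = 50, b = 10, sigma = 1) {
  integrated_gaussian_model(0:(n - 1), 0:(n - 1), mu_x, mu_y, N, b, sigma)
}
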