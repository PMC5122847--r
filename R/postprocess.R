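#' dSTORM quality filter
#'
#' Keeps localizations whose signal-to-background ratio exceeds `sbr_min`
#' and whose fitted PSF width lies within `sigma_center +- sigma_halfwidth`
#' px. The customary dSTORM settings are `sbr > 0.8` and
#' `sigma = 1.42 +- 0.4` px. Row order is preserved.
#'
#' @param locs localization table with columns `sbr` and `sigma_x`.
#' @param sbr_min strict lower bound on the signal-to-background ratio.
#' @param sigma_center,sigma_halfwidth acceptance window (px) on the
#'   fitted width, inclusive at both edges.
#' @return The filtered tibble.
#' @export
filter_localizations <- function(locs, sbr_min = 0.8, sigma_center = 1.42,
                                 sigma_halfwidth = 0.4) {
  stopifnot(sigma_halfwidth >= 0)
  locs <- tibble::as_tibble(locs)
  # tiny slack so representable widths exactly on the window edge pass
  keep <- locs$sbr > sbr_min &
    abs(locs$sigma_x - sigma_center) <= sigma_halfwidth + 1e-9
  locs[keep, , drop = FALSE]
}

#' Remove localizations belonging to long-lived tracks
#'
#' In dSTORM, emitters that stay on for many consecutive frames are
#' fluorophore clusters rather than single switching molecules. Tracks
#' with more than `max_track_length` points (strictly longer) are
#' discarded together with all their localizations; localizations not on
#' any track are kept.
#'
#' @param locs localization table.
#' @param tracks tracking [result_table()] built from `locs`, whose
#'   `loc_row` column indexes rows of `locs`.
#' @param max_track_length longest track length still considered a single
#'   molecule (frames/points).
#' @return `locs` without the clustered rows.
#' @export
discard_cluster_tracks <- function(locs, tracks, max_track_length = 25L) {
  locs <- tibble::as_tibble(locs)
  if (nrow(tracks) == 0L) return(locs)
  if (!"loc_row" %in% names(tracks)) {
    stop("`tracks` lacks the `loc_row` column linking back to `locs`",
         call. = FALSE)
  }
  len <- table(tracks$track_id)
  long_ids <- as.numeric(names(len))[as.vector(len) > max_track_length]
  drop_rows <- tracks$loc_row[tracks$track_id %in% long_ids]
  if (length(drop_rows) == 0L) return(locs)
  locs[-drop_rows, , drop = FALSE]
}

#' Super-resolution rendering
#'
#' Renders localizations into a super-resolved image. In `counts` mode
#' each localization adds 1 to its bin (a plain 2D histogram); in
#' `precision_weighted` mode each localization is splatted as a
#' unit-integral 2D Gaussian whose per-axis width is its localization
#' precision, so uncertain points spread out while precise ones stay
#' sharp. In both modes the image integral equals the number of
#' localizations (up to truncation of the Gaussian tails).
#'
#' @param locs localization table with `x`, `y` (px); weighted mode also
#'   needs `precision_x`, `precision_y` (nm).
#' @param pixel_size_nm camera pixel size (nm).
#' @param out_pixel_nm output (super-resolution) pixel size in nm;
#'   10 nm is customary.
#' @param mode `"precision_weighted"` or `"counts"`.
#' @param field_nm output extent in nm (defaults to the bounding box).
#' @return Numeric matrix (row = y bin, column = x bin) with attributes
#'   `out_pixel_nm` and `mode`.
#' @export
render_super_resolution <- function(locs, pixel_size_nm, out_pixel_nm = 10,
                                    mode = c("precision_weighted", "counts"),
                                    field_nm = NULL) {
  mode <- match.arg(mode)
  locs <- tibble::as_tibble(locs)
  x_nm <- locs$x * pixel_size_nm
  y_nm <- locs$y * pixel_size_nm
  if (mode == "precision_weighted") {
    if (!all(c("precision_x", "precision_y") %in% names(locs))) {
      stop("precision_weighted mode needs `precision_x`/`precision_y` columns",
           call. = FALSE)
    }
    if (nrow(locs) > 0L && anyNA(c(locs$precision_x, locs$precision_y))) {
      stop("missing precision values; filter non-converged fits first",
           call. = FALSE)
    }
  }
  if (is.null(field_nm)) {
    field_nm <- if (nrow(locs) == 0L) out_pixel_nm * 64 else {
      max(x_nm, y_nm) * 1.001 + out_pixel_nm
    }
  }
  n <- max(1L, ceiling(field_nm / out_pixel_nm))
  img <- matrix(0, n, n)
  if (nrow(locs) == 0L) {
    return(structure(img, out_pixel_nm = out_pixel_nm, mode = mode))
  }
  if (mode == "counts") {
    ix <- pmin(pmax(floor(x_nm / out_pixel_nm), 0), n - 1L)
    iy <- pmin(pmax(floor(y_nm / out_pixel_nm), 0), n - 1L)
    for (k in seq_along(ix)) {
      img[iy[k] + 1L, ix[k] + 1L] <- img[iy[k] + 1L, ix[k] + 1L] + 1
    }
  } else {
    # splat each localization as a pixel-integrated unit Gaussian
    for (k in seq_len(nrow(locs))) {
      sx <- locs$precision_x[k] / out_pixel_nm
      sy <- locs$precision_y[k] / out_pixel_nm
      cx <- x_nm[k] / out_pixel_nm - 0.5   # bin-center coordinates
      cy <- y_nm[k] / out_pixel_nm - 0.5
      rx <- ceiling(6 * sx) + 1; ry <- ceiling(6 * sy) + 1
      x0 <- max(0, floor(cx) - rx); x1 <- min(n - 1L, ceiling(cx) + rx)
      y0 <- max(0, floor(cy) - ry); y1 <- min(n - 1L, ceiling(cy) + ry)
      if (x1 < x0 || y1 < y0) next
      ex <- pixel_erf((x0:x1) - cx, max(sx, 1e-6))
      ey <- pixel_erf((y0:y1) - cy, max(sy, 1e-6))
      img[(y0:y1) + 1L, (x0:x1) + 1L] <- img[(y0:y1) + 1L, (x0:x1) + 1L] +
        outer(ey, ex)
    }
  }
  structure(img, out_pixel_nm = out_pixel_nm, mode = mode)
}

#' Pooled within-track displacements per lag
#'
#' For each lag `k = 1..max_lag`, collects all displacement vectors
#' between track points exactly `k` frames apart, pooled across tracks,
#' and pools the x- and y-components into one 1D sample per lag (for a
#' free 2D Brownian walk both components follow the same zero-mean
#' Gaussian). Intervals that span a bridged detection gap are excluded:
#' their true time base is ambiguous.
#'
#' @param tracks tracking [result_table()].
#' @param t_a frame acquisition time (s).
#' @param max_lag largest frame lag to collect (>= 1).
#' @return Tibble with `lag` (frames), `lag_time_s`, `component`
#'   (`"x"`/`"y"`), `displacement_px`.
#' @export
compute_displacements <- function(tracks, t_a, max_lag = 5L) {
  stopifnot(max_lag >= 1, t_a > 0)
  tracks <- tibble::as_tibble(tracks)
  out_lag <- list(); out_comp <- list(); out_d <- list(); idx <- 0L
  if (nrow(tracks) > 0L) {
    has_gaps <- "n_gaps" %in% names(tracks)
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      tr <- tr[order(tr$frame), , drop = FALSE]
      n <- nrow(tr)
      if (n < 2L) next
      for (k in seq_len(min(max_lag, n - 1L))) {
        i <- seq_len(n - k)
        j <- i + k
        ok <- (tr$frame[j] - tr$frame[i]) == k       # contiguous in time
        if (has_gaps) {
          # exclude any interval containing a bridged gap
          gap_here <- tr$n_gaps > 0
          cg <- cumsum(gap_here)
          ok <- ok & (cg[j] - cg[i] == 0)
        }
        if (!any(ok)) next
        dx <- tr$x[j[ok]] - tr$x[i[ok]]
        dy <- tr$y[j[ok]] - tr$y[i[ok]]
        idx <- idx + 1L
        out_lag[[idx]] <- rep.int(k, 2L * length(dx))
        out_comp[[idx]] <- rep(c("x", "y"), each = length(dx))
        out_d[[idx]] <- c(dx, dy)
      }
    }
  }
  if (idx == 0L) {
    return(tibble::tibble(lag = integer(0), lag_time_s = numeric(0),
                          component = character(0),
                          displacement_px = numeric(0)))
  }
  lag <- unlist(out_lag)
  tibble::tibble(
    lag = lag,
    lag_time_s = lag * t_a,
    component = unlist(out_comp),
    displacement_px = unlist(out_d)
  )
}

#' Diffusion coefficient from displacement statistics
#'
#' Per lag, a zero-mean Gaussian is fitted to the pooled per-axis
#' displacements — by default via the closed-form maximum-likelihood
#' variance (the mean of squares); a least-squares fit of a Gaussian bell
#' to the normalized displacement histogram is available as
#' `method = "histogram"` and agrees asymptotically. The per-axis
#' variances `sigma^2(k)`, converted to um^2, are then regressed on lag
#' time: `sigma^2 = 2 D (k t_a) + epsilon`, so the slope gives the
#' diffusion coefficient and the intercept `epsilon` absorbs the static
#' localization error.
#'
#' @param displacements tibble from [compute_displacements()].
#' @param pixel_size_nm camera pixel size (nm).
#' @param min_per_lag minimum pooled sample size per lag; lags below it
#'   are dropped.
#' @param min_lags minimum number of usable lags (estimation error below).
#' @param method `"mle"` (default) or `"histogram"`.
#' @param n_bins histogram bins for `method = "histogram"`.
#' @return A `diffusion_fit` list: `lags` tibble (`lag`, `lag_time_s`,
#'   `sigma2_um2`, `n`), `D_um2_s`, `epsilon_um2`, `D_stderr`,
#'   `negative_D` flag.
#' @export
estimate_diffusion <- function(displacements, pixel_size_nm,
                               min_per_lag = 50L, min_lags = 3L,
                               method = c("mle", "histogram"),
                               n_bins = 41L) {
  method <- match.arg(method)
  d <- tibble::as_tibble(displacements)
  if (nrow(d) == 0L) stop("no displacements supplied", call. = FALSE)
  px_um <- pixel_size_nm / 1000
  lags <- sort(unique(d$lag))
  rows <- lapply(lags, function(k) {
    v <- d$displacement_px[d$lag == k]
    if (length(v) < min_per_lag) return(NULL)
    s2_px <- if (method == "mle") {
      mean(v^2)
    } else {
      gaussian_histogram_variance(v, n_bins)
    }
    tibble::tibble(lag = k, lag_time_s = d$lag_time_s[d$lag == k][1L],
                   sigma2_um2 = s2_px * px_um^2, n = length(v))
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) < min_lags) {
    stop(sprintf(
      "only %d lag(s) have >= %d displacements; %d required",
      nrow(rows), min_per_lag, min_lags), call. = FALSE)
  }
  if (all(rows$sigma2_um2 == 0)) {
    fit <- list(D = 0, eps = 0, se = 0)
  } else {
    lm_fit <- stats::lm(sigma2_um2 ~ lag_time_s, data = rows)
    co <- stats::coef(lm_fit)
    # an exactly linear input makes the residual stderr degenerate; that is
    # a legitimate use here, not a modelling problem
    se <- tryCatch(
      suppressWarnings(summary(lm_fit)$coefficients["lag_time_s", "Std. Error"]),
      error = function(e) NA_real_
    )
    fit <- list(D = unname(co[2L]) / 2, eps = unname(co[1L]), se = se / 2)
  }
  structure(
    list(lags = rows, D_um2_s = fit$D, epsilon_um2 = fit$eps,
         D_stderr = fit$se, negative_D = fit$D < 0),
    class = "diffusion_fit"
  )
}

# least-squares Gaussian bell on the normalized displacement histogram
gaussian_histogram_variance <- function(v, n_bins) {
  s0 <- sqrt(mean(v^2))
  if (s0 == 0) return(0)
  br <- seq(-5 * s0, 5 * s0, length.out = n_bins + 1L)
  v_cl <- pmin(pmax(v, br[1L]), br[n_bins + 1L])
  h <- graphics::hist(v_cl, breaks = br, plot = FALSE)
  dens <- h$density
  mids <- h$mids
  obj <- function(ls) sum((dens - stats::dnorm(mids, 0, exp(ls)))^2)
  exp(stats::optimize(obj, log(s0) + c(-2, 2))$minimum)^2
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> D = %.4g um^2/s (stderr %.2g), epsilon = %.3g um^2, %d lag(s)%s\n",
    x$D_um2_s, x$D_stderr, x$epsilon_um2, nrow(x$lags),
    if (x$negative_D) " [negative D estimate]" else ""
  ))
  invisible(x)
}
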