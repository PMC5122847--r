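#' @name simulator
#' @title Synthetic SMLM and tracking movies with known ground truth
#'
#' @description
#' The simulator produces the three test-bed datasets used throughout the
#' package: a Siemens-star dSTORM movie with blinking and photobleaching
#' kinetics, a regular emitter-grid movie for throughput testing, and
#' Brownian-motion movies for the tracking/diffusion chain. Every generator
#' takes an explicit seed and is bit-reproducible.
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Optics / photometry configuration
#'
#' @param lambda_em emission wavelength (nm).
#' @param NA_ numerical aperture.
#' @param pixel_size_nm camera pixel size (nm).
#' @param N_photons photons per frame emitted by a fully active emitter.
#' @param background background photons per pixel per frame.
#' @return A list with the fields above plus `sigma_px`, the PSF width
#'   from [psf_sigma_from_optics()].
#' @export
optics_config <- function(lambda_em = 670, NA_ = 1.4, pixel_size_nm = 100,
                          N_photons = 50, background = 10) {
  stopifnot(lambda_em > 0, NA_ > 0, pixel_size_nm > 0, N_photons > 0,
            background >= 0)
  list(lambda_em = lambda_em, NA_ = NA_, pixel_size_nm = pixel_size_nm,
       N_photons = N_photons, background = background,
       sigma_px = psf_sigma_from_optics(lambda_em, NA_, pixel_size_nm))
}

#' Blinking / bleaching kinetics
#'
#' Two-state telegraph model with photobleaching: an emitter alternates
#' exponentially distributed dark (rate `k_on`) and active (rate
#' `k_deactivate = k_off + k_bleach`) periods; at the end of each active
#' period it bleaches with probability `p_bleach = k_bleach/k_deactivate`,
#' so the number of activations until bleaching is geometric. The derived
#' mean cycle time obeys `1/k_active = 1/k_deactivate + 1/k_on`.
#'
#' @param k_on activation rate (frame^-1); 0 means never activates.
#' @param k_off deactivation (off-switching) rate (frame^-1).
#' @param k_bleach bleaching rate (frame^-1).
#' @return A `blink_kinetics` list with the rates and derived quantities
#'   `k_deactivate`, `p_bleach`, `k_active`.
#' @export
blink_kinetics <- function(k_on, k_off = 1, k_bleach = 0.15) {
  stopifnot(k_on >= 0, k_off >= 0, k_bleach >= 0)
  k_deact <- k_off + k_bleach
  if (k_deact <= 0) stop("k_off + k_bleach must be positive", call. = FALSE)
  structure(
    list(k_on = k_on, k_off = k_off, k_bleach = k_bleach,
         k_deactivate = k_deact,
         p_bleach = k_bleach / k_deact,
         k_active = if (k_on > 0) 1 / (1 / k_deact + 1 / k_on) else 0),
    class = "blink_kinetics"
  )
}

#' Emitter positions on a Siemens star
#'
#' Places emitters uniformly at random inside the filled arms of an n-arm
#' Siemens star (alternating angular sectors of width `pi/n`) inscribed in
#' the square grid. Positions are continuous (sub-pixel). The emitter
#' count is drawn Poisson with mean `rho * grid` (the density parameter is
#' read against the linear grid extent) unless `n_emitters` fixes it.
#'
#' @param n_arms number of star arms (>= 1).
#' @param grid grid edge length in px.
#' @param rho emitter density parameter (px^-1).
#' @param seed RNG seed.
#' @param n_emitters optional exact emitter count, overriding `rho`.
#' @return Tibble with `emitter_id`, `mu_x`, `mu_y` (0-based px).
#' @export
siemens_star_positions <- function(n_arms = 10, grid = 256, rho = 7.5,
                                   seed = 1, n_emitters = NULL) {
  stopifnot(n_arms >= 1, grid > 0)
  with_seed(seed, {
    n <- if (is.null(n_emitters)) stats::rpois(1, rho * grid) else n_emitters
    cx <- (grid - 1) / 2
    radius <- grid / 2
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(64L, 2L * (n - length(xs)))
      x <- stats::runif(m, 0, grid - 1)
      y <- stats::runif(m, 0, grid - 1)
      dx <- x - cx; dy <- y - cx
      r <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx) %% (2 * pi)
      keep <- r <= radius & (floor(ang / (pi / n_arms)) %% 2 == 0)
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
    }
    tibble::tibble(emitter_id = seq_len(n),
                   mu_x = xs[seq_len(n)], mu_y = ys[seq_len(n)])
  })
}

#' Whether points lie inside the "on" sectors of a Siemens star
#'
#' @param x,y positions (0-based px).
#' @param n_arms,grid star geometry as in [siemens_star_positions()].
#' @return Logical vector.
#' @export
in_siemens_arm <- function(x, y, n_arms = 10, grid = 256) {
  cx <- (grid - 1) / 2
  dx <- x - cx; dy <- y - cx
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  r <= grid / 2 & (floor(ang / (pi / n_arms)) %% 2 == 0)
}

#' Simulate blinking and bleaching of static emitters
#'
#' Continuous-time simulation of the [blink_kinetics()] model. Every
#' emitter starts dark; active intervals are intersected with the frame
#' grid to yield the active fraction `A` of each frame. Emitters emit no
#' rows after their bleaching event or outside their active periods.
#'
#' @param positions tibble from [siemens_star_positions()] (or any table
#'   with `emitter_id`, `mu_x`, `mu_y`).
#' @param kinetics a [blink_kinetics()].
#' @param n_frames movie length in frames.
#' @param seed RNG seed.
#' @param keep_events also record the underlying activation events; they
#'   are attached as attribute `"events"`: a tibble of `emitter_id`,
#'   `t_start`, `duration` (untruncated, frames) and `bleached`.
#' @return Ground-truth tibble `(frame, emitter_id, mu_x, mu_y, A)` with
#'   `A` in `(0, 1]`, sorted by `(frame, emitter_id)`.
#' @export
simulate_blinking <- function(positions, kinetics, n_frames, seed = 1,
                              keep_events = FALSE) {
  stopifnot(inherits(kinetics, "blink_kinetics"), n_frames >= 1)
  if (kinetics$k_on == 0) {
    return(tibble::tibble(frame = numeric(0), emitter_id = integer(0),
                          mu_x = numeric(0), mu_y = numeric(0), A = numeric(0)))
  }
  with_seed(seed, {
    rows_frame <- list(); rows_id <- list(); rows_A <- list()
    ev_id <- list(); ev_start <- list(); ev_dur <- list(); ev_bl <- list()
    n_em <- nrow(positions)
    for (i in seq_len(n_em)) {
      t <- stats::rexp(1, kinetics$k_on)
      starts <- numeric(0); ends <- numeric(0); durs <- numeric(0)
      bleached <- FALSE
      while (t < n_frames) {
        dur <- stats::rexp(1, kinetics$k_deactivate)
        starts <- c(starts, t)
        ends <- c(ends, min(t + dur, n_frames))
        durs <- c(durs, dur)
        t <- t + dur
        if (stats::runif(1) < kinetics$p_bleach) { bleached <- TRUE; break }
        t <- t + stats::rexp(1, kinetics$k_on)
      }
      if (keep_events && length(starts) > 0L) {
        ev_id[[i]] <- rep.int(positions$emitter_id[i], length(starts))
        ev_start[[i]] <- starts
        ev_dur[[i]] <- durs
        ev_bl[[i]] <- c(rep(FALSE, length(starts) - 1L), bleached)
      }
      if (length(starts) == 0L) next
      # active fraction per frame: overlap of [f, f+1) with active intervals
      f_lo <- floor(starts); f_hi <- ceiling(ends) - 1
      touched <- unique(unlist(mapply(seq, f_lo, pmin(f_hi, n_frames - 1),
                                      SIMPLIFY = FALSE)))
      A <- vapply(touched, function(f) {
        sum(pmax(0, pmin(ends, f + 1) - pmax(starts, f)))
      }, numeric(1))
      keep <- A > 0
      rows_frame[[i]] <- touched[keep]
      rows_id[[i]] <- rep.int(i, sum(keep))
      rows_A[[i]] <- A[keep]
    }
    frame <- unlist(rows_frame); id <- unlist(rows_id); A <- unlist(rows_A)
    if (is.null(frame)) frame <- numeric(0)
    out <- tibble::tibble(
      frame = as.numeric(frame),
      emitter_id = positions$emitter_id[id],
      mu_x = positions$mu_x[id],
      mu_y = positions$mu_y[id],
      A = pmin(A, 1)
    )
    out <- out[order(out$frame, out$emitter_id), ]
    if (keep_events) {
      attr(out, "events") <- tibble::tibble(
        emitter_id = unlist(ev_id) %||0% integer(0),
        t_start = unlist(ev_start) %||0% numeric(0),
        duration = unlist(ev_dur) %||0% numeric(0),
        bleached = unlist(ev_bl) %||0% logical(0)
      )
    }
    out
  })
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# add one integrated-Gaussian spot of total intensity amp to `img`
# (modified in place by the caller via returned matrix)
add_spots <- function(img, mu_x, mu_y, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(6 * sigma) + 2
  for (k in seq_along(mu_x)) {
    x0 <- max(0, floor(mu_x[k]) - r); x1 <- min(w - 1, ceiling(mu_x[k]) + r)
    y0 <- max(0, floor(mu_y[k]) - r); y1 <- min(h - 1, ceiling(mu_y[k]) + r)
    if (x1 < x0 || y1 < y0) next
    ex <- pixel_erf((x0:x1) - mu_x[k], sigma)
    ey <- pixel_erf((y0:y1) - mu_y[k], sigma)
    img[(y0:y1) + 1L, (x0:x1) + 1L] <- img[(y0:y1) + 1L, (x0:x1) + 1L] +
      amp[k] * outer(ey, ex)
  }
  img
}

# peak-pixel fraction of a unit spot at sub-pixel position (mu_x, mu_y)
peak_fraction <- function(mu_x, mu_y, sigma) {
  pixel_erf(round(mu_x) - mu_x, sigma) * pixel_erf(round(mu_y) - mu_y, sigma)
}

# scale factor on N so the mean emitter SNR s/sqrt(s + b) hits the target
snr_scale <- function(peak_signals, b, target_snr) {
  f <- function(a) mean(a * peak_signals / sqrt(a * peak_signals + b)) - target_snr
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Render a ground-truth emitter list into a noisy movie
#'
#' Expected image per frame: `b + sum_i A_i N g(mu_i)` with `g` the
#' pixel-integrated Gaussian of width [psf_sigma_from_optics()]. When
#' `target_snr` is given, the photon yield is rescaled globally so that the
#' mean over active emitter instances of the peak signal-to-noise ratio
#' `s/sqrt(s + b)` (shot-noise form) equals the target. Pixel values are
#' then drawn Poisson from the expected image.
#'
#' @param truth ground-truth tibble `(frame, mu_x, mu_y, A)` (emitter_id
#'   optional).
#' @param optics an [optics_config()].
#' @param n_frames movie length; defaults to `max(truth$frame) + 1`.
#' @param dims `c(H, W)` frame shape in px.
#' @param target_snr desired mean SNR, or `NULL` to keep `N_photons` as is.
#' @param seed RNG seed for the Poisson noise.
#' @return List: `movie` (a photon-unit [movie_stack()]), `reference`
#'   (noiseless T x H x W expected-value array), `N_eff` (photon yield
#'   after SNR normalization), `snr_scale`.
#' @export
render_movie <- function(truth, optics, n_frames = NULL, dims = c(256L, 256L),
                         target_snr = NULL, seed = 1) {
  if (!is.null(target_snr) && target_snr <= 0) {
    stop("`target_snr` must be positive", call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(truth) > 0L) max(truth$frame) + 1L else 1L
  }
  if (nrow(truth) > 0L && max(truth$frame) >= n_frames) {
    stop("ground truth extends beyond the movie length", call. = FALSE)
  }
  sigma <- optics$sigma_px
  b <- optics$background
  scale <- 1
  if (!is.null(target_snr) && nrow(truth) > 0L) {
    peaks <- truth$A * optics$N_photons *
      peak_fraction(truth$mu_x, truth$mu_y, sigma)
    scale <- snr_scale(peaks, b, target_snr)
  }
  N_eff <- optics$N_photons * scale
  reference <- array(b, dim = c(n_frames, dims[1L], dims[2L]))
  if (nrow(truth) > 0L) {
    for (f in unique(truth$frame)) {
      sel <- truth$frame == f
      img <- matrix(reference[f + 1L, , ], dims[1L])
      img <- add_spots(img, truth$mu_x[sel], truth$mu_y[sel],
                       truth$A[sel] * N_eff, sigma)
      reference[f + 1L, , ] <- img
    }
  }
  noisy <- with_seed(seed, {
    array(stats::rpois(length(reference), reference), dim = dim(reference))
  })
  list(
    movie = movie_stack(noisy, pixel_size_nm = optics$pixel_size_nm,
                        unit = "photons"),
    reference = reference,
    N_eff = N_eff,
    snr_scale = scale
  )
}

#' Siemens-star dSTORM movie preset
#'
#' Convenience composition of [siemens_star_positions()],
#' [simulate_blinking()] and [render_movie()] under STORM-like default
#' conditions: a 10-arm star on a 256 x 256 px grid at 100 nm pixels,
#' photon yield 50, background 10 photons/px, emission 670 nm at NA 1.4,
#' rates `k_off` = 1, `k_bleach` = 0.15 and `k_on = k_off/(5 rho)`
#' frame^-1 with `rho` = 7.5, movie length 1500 frames. All parameters
#' can be overridden.
#'
#' @param grid grid edge (px).
#' @param n_frames movie length.
#' @param n_arms star arms.
#' @param rho emitter density parameter (px^-1).
#' @param n_emitters optional exact emitter count.
#' @param target_snr mean SNR to normalize to, or `NULL` for raw photons.
#' @param optics an [optics_config()].
#' @param k_off,k_bleach kinetics rates (frame^-1); `k_on` is derived as
#'   `k_off/(5 rho)` unless given.
#' @param k_on activation rate override.
#' @param seed RNG seed (stages use seed, seed+1, seed+2).
#' @param render set `FALSE` to skip rendering (ground truth only).
#' @return List: `movie`, `reference`, `truth`, `positions`, `optics`,
#'   `kinetics`, `N_eff`.
#' @export
make_siemens_movie <- function(grid = 256L, n_frames = 1500L, n_arms = 10,
                               rho = 7.5, n_emitters = NULL,
                               target_snr = NULL,
                               optics = optics_config(),
                               k_off = 1, k_bleach = 0.15,
                               k_on = k_off / (5 * rho),
                               seed = 1, render = TRUE) {
  pos <- siemens_star_positions(n_arms, grid, rho, seed = seed,
                                n_emitters = n_emitters)
  kin <- blink_kinetics(k_on = k_on, k_off = k_off, k_bleach = k_bleach)
  truth <- simulate_blinking(pos, kin, n_frames, seed = seed + 1L)
  out <- list(truth = truth, positions = pos, optics = optics, kinetics = kin)
  if (render) {
    ren <- render_movie(truth, optics, n_frames = n_frames,
                        dims = c(grid, grid), target_snr = target_snr,
                        seed = seed + 2L)
    out <- c(list(movie = ren$movie, reference = ren$reference,
                  N_eff = ren$N_eff), out)
  }
  out
}

#' Regular emitter-grid movie (throughput preset)
#'
#' One frame of `n_side x n_side` always-active emitters placed at regular
#' intervals is rendered and duplicated: the expected image is reused for
#' every frame while the Poisson noise is re-drawn per frame. With the
#' defaults (512 px frame, 16 x 16 emitters, 3500 frames) the ground
#' truth holds 896,000 particle instances.
#'
#' @param grid frame edge (px).
#' @param n_side emitters per side.
#' @param n_frames number of duplicated frames.
#' @param target_snr mean SNR normalization target.
#' @param optics an [optics_config()].
#' @param seed RNG seed.
#' @param render set `FALSE` for ground truth only.
#' @return List: `movie` (when rendered), `reference_frame` (H x W
#'   expected image), `truth`, `positions`, `N_eff`.
#' @export
make_grid_movie <- function(grid = 512L, n_side = 16L, n_frames = 3500L,
                            target_snr = 10, optics = optics_config(),
                            seed = 1, render = TRUE) {
  spacing <- grid / n_side
  if (spacing < 8 * optics$sigma_px) {
    stop("emitter spacing below 8 PSF widths; grid too dense", call. = FALSE)
  }
  centers <- spacing * (seq_len(n_side) - 0.5) - 0.5   # 0-based px
  pos <- tidyr::expand_grid(mu_y = centers, mu_x = centers)
  pos <- tibble::tibble(emitter_id = seq_len(nrow(pos)),
                        mu_x = pos$mu_x, mu_y = pos$mu_y)
  truth <- tibble::tibble(
    frame = rep(0:(n_frames - 1L), each = nrow(pos)),
    emitter_id = rep(pos$emitter_id, n_frames),
    mu_x = rep(pos$mu_x, n_frames),
    mu_y = rep(pos$mu_y, n_frames),
    A = 1
  )
  out <- list(truth = truth, positions = pos, optics = optics)
  if (render) {
    # render one expected frame, duplicate it, re-draw noise per frame
    one <- truth[truth$frame == 0, ]
    peaks <- optics$N_photons * peak_fraction(one$mu_x, one$mu_y,
                                              optics$sigma_px)
    scale <- if (is.null(target_snr)) 1 else {
      snr_scale(peaks, optics$background, target_snr)
    }
    N_eff <- optics$N_photons * scale
    ref <- add_spots(matrix(optics$background, grid, grid),
                     one$mu_x, one$mu_y, rep(N_eff, nrow(one)),
                     optics$sigma_px)
    noisy <- with_seed(seed, {
      array(stats::rpois(n_frames * grid * grid,
                         rep(as.vector(ref), each = n_frames)),
            dim = c(n_frames, grid, grid))
    })
    out <- c(list(
      movie = movie_stack(noisy, pixel_size_nm = optics$pixel_size_nm,
                          unit = "photons"),
      reference_frame = ref, N_eff = N_eff
    ), out)
  }
  out
}

#' Brownian-motion tracking movie
#'
#' Particles perform independent 2D Brownian motion with per-axis step
#' variance `2 D t_a` (reflected at the frame borders) and are rendered
#' with the same photometry as the other presets. The true trajectories
#' are returned as a tracking table for direct comparison with the
#' linker's output.
#'
#' @param D diffusion coefficient (um^2/s, >= 0).
#' @param t_a frame acquisition time (s).
#' @param n_particles,n_frames scene size.
#' @param optics an [optics_config()].
#' @param dims `c(H, W)` frame shape (px).
#' @param target_snr mean SNR normalization target (or `NULL`).
#' @param seed RNG seed.
#' @param render set `FALSE` to skip rendering.
#' @return List: `movie` (when rendered), `truth_tracks` (tracking
#'   [result_table()]), `optics`, `step_sd_px`, `N_eff`.
#' @export
simulate_brownian_movie <- function(D, t_a, n_particles = 50L, n_frames = 100L,
                                    optics = optics_config(pixel_size_nm = 108),
                                    dims = c(256L, 256L), target_snr = 5,
                                    seed = 1, render = TRUE) {
  stopifnot(D >= 0, t_a > 0, n_particles >= 1, n_frames >= 1)
  step_sd_px <- sqrt(2 * D * t_a) * 1000 / optics$pixel_size_nm
  pos <- with_seed(seed, {
    x <- matrix(0, n_frames, n_particles)
    y <- matrix(0, n_frames, n_particles)
    x[1L, ] <- stats::runif(n_particles, 0, dims[2L] - 1)
    y[1L, ] <- stats::runif(n_particles, 0, dims[1L] - 1)
    if (n_frames > 1L) {
      for (f in 2:n_frames) {
        x[f, ] <- reflect_coord(x[f - 1L, ] +
                                  stats::rnorm(n_particles, 0, step_sd_px),
                                dims[2L] - 1)
        y[f, ] <- reflect_coord(y[f - 1L, ] +
                                  stats::rnorm(n_particles, 0, step_sd_px),
                                dims[1L] - 1)
      }
    }
    list(x = x, y = y)
  })
  truth_tracks <- tibble::tibble(
    track_id = as.numeric(rep(seq_len(n_particles), each = n_frames)),
    frame = as.numeric(rep(0:(n_frames - 1L), n_particles)),
    x = as.vector(pos$x),
    y = as.vector(pos$y)
  )
  truth_tracks <- sort_stage_table(result_table(truth_tracks, "tracking"),
                                   "tracking")
  out <- list(truth_tracks = truth_tracks, optics = optics,
              step_sd_px = step_sd_px)
  if (render) {
    truth <- tibble::tibble(frame = truth_tracks$frame,
                            mu_x = truth_tracks$x, mu_y = truth_tracks$y,
                            A = 1)
    ren <- render_movie(truth, optics, n_frames = n_frames, dims = dims,
                        target_snr = target_snr, seed = seed + 1L)
    ren$movie$frame_time_s <- t_a
    out <- c(list(movie = ren$movie, N_eff = ren$N_eff), out)
  }
  out
}

reflect_coord <- function(v, upper) {
  repeat {
    below <- v < 0; above <- v > upper
    if (!any(below) && !any(above)) return(v)
    v[below] <- -v[below]
    v[above] <- 2 * upper - v[above]
  }
}
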