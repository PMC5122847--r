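#' @name detection-filters
#' @title Candidate detection filters
#'
#' @description
#' Stage 2 turns each frame into a score image in which bright,
#' diffraction-limited spots stand out from the background, then extracts
#' thresholded local maxima as rough candidate positions. Three filters are
#' provided: a band-pass (difference of Gaussian smoothings), normalized
#' cross-correlation against a pixel-integrated Gaussian PSF template, and
#' the a-trous (undecimated) B3-spline wavelet transform whose second
#' detail plane isolates spot-scale structure. All convolutions use mirror
#' boundary padding, which avoids spurious maxima at the frame edge.
NULL

# reflect out-of-range 1-based indices back into [1, n] (whole-sample
# mirror about the boundary samples); iterates so kernels wider than the
# image still resolve
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    below <- i < 1L
    above <- i > n
    if (!any(below) && !any(above)) return(i)
    i[below] <- 2L - i[below]
    i[above] <- 2L * n - i[above]
  }
}

# separable convolution with a symmetric 1D kernel, optionally with holes
# (taps spaced `step` pixels apart, the a-trous scheme)
conv_sep <- function(img, kernel, step = 1L) {
  r <- (length(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (t in seq_along(kernel)) {           # along rows (y)
    idx <- reflect_index(seq_len(h) + (t - 1L - r) * step, h)
    out <- out + kernel[t] * img[idx, , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (t in seq_along(kernel)) {           # along columns (x)
    idx <- reflect_index(seq_len(w) + (t - 1L - r) * step, w)
    out2 <- out2 + kernel[t] * out[, idx, drop = FALSE]
  }
  out2
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(( -r:r )^2) / (2 * sigma^2))
  k / sum(k)
}

box_kernel <- function(len) rep(1, len)

score_image <- function(values, origin, threshold_rule, threshold = NA_real_) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(values, class = c("score_image", "matrix", "array"),
            origin = origin, threshold_rule = threshold_rule,
            threshold = threshold)
}

#' @describeIn detection-filters band-pass: difference of a small-scale and
#'   a large-scale Gaussian smoothing. Both kernels are normalized, so the
#'   response to a constant frame is exactly zero (the filter removes DC).
#' @param frame an `H x W` numeric matrix (one movie frame).
#' @param feature_size Gaussian sigma (px) of the small-scale smoothing,
#'   matched to the spot size.
#' @param background_size Gaussian sigma (px) of the large-scale smoothing
#'   estimating the background; must exceed `feature_size`.
#' @return A `score_image`: an `H x W` matrix with attributes `origin` and
#'   `threshold_rule` (and `threshold` where the filter defines one).
#' @export
bandpass_filter <- function(frame, feature_size = 1, background_size = 4) {
  if (!(feature_size > 0 && feature_size < background_size)) {
    stop("need 0 < feature_size < background_size", call. = FALSE)
  }
  sm <- conv_sep(frame, gauss_kernel(feature_size))
  lg <- conv_sep(frame, gauss_kernel(background_size))
  score_image(sm - lg, origin = "bandpass",
              threshold_rule = "absolute threshold on band-pass response")
}

#' @describeIn detection-filters normalized cross-correlation of every
#'   window-sized patch against a pixel-integrated Gaussian PSF template of
#'   width `sigma_psf`. Scores lie in `[-1, 1]` and are invariant to adding
#'   a constant to the frame; patches with zero variance score 0.
#' @param sigma_psf PSF standard deviation in px.
#' @param window odd template edge length in px; `2*ceiling(3*sigma)+1`
#'   or larger recommended.
#' @export
crosscorr_score <- function(frame, sigma_psf = 1, window = 2L * ceiling(3 * sigma_psf) + 1L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window > min(dim(frame))) {
    stop("`window` larger than the frame", call. = FALSE)
  }
  # removing the global mean leaves the score unchanged mathematically but
  # avoids catastrophic cancellation in the local-variance term, making the
  # additive-offset invariance exact
  frame <- frame - mean(frame)
  tmpl <- integrated_gaussian_template(sigma_psf, window)
  tm <- mean(tmpl)
  t0_ss <- sum((tmpl - tm)^2)
  n <- window^2
  g1 <- tmpl_profile(sigma_psf, window)   # separable 1D factor
  # conv(frame, template) via separability (template = g1 %o% g1)
  ft <- conv_sep_kernel2(frame, g1, g1)
  fbox <- conv_sep(frame, box_kernel(window))
  f2box <- conv_sep(frame^2, box_kernel(window))
  num <- ft - tm * fbox                       # sum f * (t - mean t)
  varf <- pmax(f2box - fbox^2 / n, 0)         # n * local variance
  denom <- sqrt(varf * t0_ss)
  sc <- ifelse(denom > 1e-12 * max(1, max(abs(frame))), num / denom, 0)
  sc <- pmin(pmax(sc, -1), 1)
  score_image(matrix(sc, nrow(frame)), origin = "crosscorr",
              threshold_rule = "absolute threshold on correlation coefficient")
}

# separable convolution with distinct row/column kernels
conv_sep_kernel2 <- function(img, ky, kx) {
  r <- (length(ky) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (t in seq_along(ky)) {
    idx <- reflect_index(seq_len(h) + (t - 1L - r), h)
    out <- out + ky[t] * img[idx, , drop = FALSE]
  }
  r <- (length(kx) - 1L) %/% 2L
  out2 <- matrix(0, h, w)
  for (t in seq_along(kx)) {
    idx <- reflect_index(seq_len(w) + (t - 1L - r), w)
    out2 <- out2 + kx[t] * out[, idx, drop = FALSE]
  }
  out2
}

# 1D pixel-integrated Gaussian profile centered on the middle pixel
tmpl_profile <- function(sigma, window) {
  r <- (window - 1L) / 2
  centers <- (-r):r
  s2 <- sqrt(2) * sigma
  0.5 * (erf((centers + 0.5) / s2) - erf((centers - 0.5) / s2))
}

integrated_gaussian_template <- function(sigma, window) {
  g <- tmpl_profile(sigma, window)
  outer(g, g)
}

#' A-trous B3-spline wavelet decomposition
#'
#' Undecimated wavelet transform with the B3-spline kernel
#' `(1, 4, 6, 4, 1)/16`, inserting `2^(j-1) - 1` zeros between taps at
#' level `j`. The detail planes plus the final smooth plane reconstruct
#' the input exactly.
#'
#' @param frame an `H x W` numeric matrix.
#' @param levels number of detail planes (>= 2 for [wavelet_filter()]).
#' @return List with `details` (list of `levels` matrices) and `smooth`
#'   (the residual low-pass plane).
#' @export
atrous_decompose <- function(frame, levels = 3L) {
  h <- c(1, 4, 6, 4, 1) / 16
  smooth <- frame
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    nxt <- conv_sep(smooth, h, step = 2L^(j - 1L))
    details[[j]] <- smooth - nxt
    smooth <- nxt
  }
  list(details = details, smooth = smooth)
}

#' @describeIn detection-filters the 2nd detail plane of the a-trous
#'   B3-spline wavelet transform, whose scale matches diffraction-limited
#'   spots. The stored `threshold` is `k_sigma` times a robust estimate of
#'   the noise standard deviation taken from the 1st (finest) detail plane,
#'   `median(|d1|)/0.6745`.
#' @param levels number of decomposition levels (>= 2).
#' @param k_sigma threshold multiplier applied to the noise estimate.
#' @export
wavelet_filter <- function(frame, levels = 3L, k_sigma = 2) {
  if (levels < 2L) stop("wavelet filtering needs `levels` >= 2", call. = FALSE)
  support <- (2L^(levels - 1L)) * 4L + 1L
  if (min(dim(frame)) < 3L) {
    stop(sprintf("frame smaller than the level-%d kernel support (%d px)",
                 levels, support), call. = FALSE)
  }
  dec <- atrous_decompose(frame, levels)
  noise_sd <- stats::median(abs(dec$details[[1L]])) / 0.6745
  score_image(dec$details[[2L]], origin = "wavelet",
              threshold_rule = sprintf(
                "k_sigma (%g) x robust std of finest detail plane", k_sigma),
              threshold = k_sigma * noise_sd)
}

#' Extract candidate spots from a score image
#'
#' Finds integer-pixel local maxima (value equal to the 3x3 neighborhood
#' maximum) with score strictly above `threshold`, then suppresses maxima
#' closer than `min_distance` px to a stronger one. Ties in score are
#' broken towards smaller `(y, x)`. Maxima within `exclude_border` px of
#' the frame edge are dropped so that a refinement window always fits.
#'
#' @param score a `score_image` or plain matrix.
#' @param threshold strict lower bound on the score; defaults to the score
#'   image's own `threshold` attribute when present.
#' @param min_distance minimum separation between kept maxima (px, >= 1).
#' @param exclude_border border margin in px within which candidates are
#'   discarded (typically `floor(fit_window/2)`).
#' @param frame frame index recorded in the output rows.
#' @return A detection [result_table()] with columns `frame`, `x`, `y`,
#'   `score`, sorted by `(y, x)`.
#' @export
find_candidates <- function(score, threshold = NULL, min_distance = 3,
                            exclude_border = 0L, frame = 0L) {
  if (is.null(threshold)) threshold <- attr(score, "threshold")
  if (is.null(threshold) || is.na(threshold)) {
    stop("no `threshold` given and the score image carries none", call. = FALSE)
  }
  if (min_distance < 1) stop("`min_distance` must be >= 1", call. = FALSE)
  v <- unclass(score)
  attributes(v) <- list(dim = dim(score))
  h <- nrow(v); w <- ncol(v)
  # 3x3 neighborhood maximum via two directional passes (-Inf beyond edge)
  rowmax <- pmax(v,
                 rbind(matrix(-Inf, 1L, w), v[-h, , drop = FALSE]),
                 rbind(v[-1L, , drop = FALSE], matrix(-Inf, 1L, w)))
  nbmax <- pmax(rowmax,
                cbind(matrix(-Inf, h, 1L), rowmax[, -w, drop = FALSE]),
                cbind(rowmax[, -1L, drop = FALSE], matrix(-Inf, h, 1L)))
  is_max <- (v >= nbmax) & (v > threshold)
  idx <- which(is_max, arr.ind = TRUE)
  out <- empty_candidates(frame)
  if (nrow(idx) > 0L) {
    cand <- tibble::tibble(
      y = idx[, 1L] - 1, x = idx[, 2L] - 1,
      score = v[idx]
    )
    if (exclude_border > 0L) {
      keep <- cand$x >= exclude_border & cand$x < w - exclude_border &
        cand$y >= exclude_border & cand$y < h - exclude_border
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) > 0L) {
      # strongest first; equal scores towards smaller (y, x)
      cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
      keep <- logical(nrow(cand))
      kx <- numeric(0); ky <- numeric(0)
      for (i in seq_len(nrow(cand))) {
        if (length(kx) == 0L ||
            all((cand$x[i] - kx)^2 + (cand$y[i] - ky)^2 >= min_distance^2)) {
          keep[i] <- TRUE
          kx <- c(kx, cand$x[i]); ky <- c(ky, cand$y[i])
        }
      }
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[order(cand$y, cand$x), , drop = FALSE]
      out <- tibble::tibble(frame = rep(as.numeric(frame), nrow(cand)),
                            x = cand$x, y = cand$y, score = cand$score)
    }
  }
  result_table(out, "detection")
}

empty_candidates <- function(frame) {
  tibble::tibble(frame = numeric(0), x = numeric(0), y = numeric(0),
                 score = numeric(0))
}

# error function in terms of pnorm (base R has no erf)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
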