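#' Match localizations against ground truth
#'
#' Within each frame, truth and found positions are paired by a
#' minimum-total-distance one-to-one assignment restricted to pairs closer
#' than `radius` (optimal assignment, the same machinery as the track
#' linker, so the pairing is order-independent). Paired points are true
#' positives; unpaired found points are false positives and unpaired truth
#' points false negatives. The Jaccard index is
#' `TP / (TP + FN + FP)` and the RMSE the root mean squared pair distance.
#'
#' @param truth data frame of true positions: `frame`, `x`, `y` (or
#'   `mu_x`/`mu_y`, accepted as aliases).
#' @param found data frame of observed localizations: `frame`, `x`, `y`.
#' @param radius pairing radius in px (> 0); the conventional default is
#'   twice the PSF width.
#' @param pixel_size_nm when given, RMSE is also reported in nm.
#' @return A `match_result` list: `pairs` (tibble of `truth_row`,
#'   `found_row`, `distance`), counts `n_tp`, `n_fp`, `n_fn`, `jaccard`,
#'   `rmse_px` (and `rmse_nm` when the pixel size is known), and
#'   `degenerate` (`TRUE` when both sets were empty: Jaccard 1, RMSE
#'   reported 0).
#' @export
match_localizations <- function(truth, found, radius, pixel_size_nm = NA_real_) {
  stopifnot(radius > 0)
  truth <- normalize_positions(truth)
  found <- normalize_positions(found)
  n_t <- nrow(truth); n_f <- nrow(found)
  if (n_t == 0L && n_f == 0L) {
    return(new_match_result(
      pairs = tibble::tibble(truth_row = integer(0), found_row = integer(0),
                             distance = numeric(0)),
      n_tp = 0L, n_fp = 0L, n_fn = 0L, jaccard = 1, rmse_px = 0,
      pixel_size_nm = pixel_size_nm, degenerate = TRUE
    ))
  }
  pair_t <- integer(0); pair_f <- integer(0); pair_d <- numeric(0)
  frames <- union(unique(truth$frame), unique(found$frame))
  for (f in frames) {
    it <- which(truth$frame == f)
    jf <- which(found$frame == f)
    if (length(it) == 0L || length(jf) == 0L) next
    d <- sqrt(outer(truth$x[it], found$x[jf], `-`)^2 +
                outer(truth$y[it], found$y[jf], `-`)^2)
    allowed <- d <= radius
    if (!any(allowed)) next
    m <- solve_assignment(d, allowed)
    hit <- which(!is.na(m))
    pair_t <- c(pair_t, it[hit])
    pair_f <- c(pair_f, jf[m[hit]])
    pair_d <- c(pair_d, d[cbind(hit, m[hit])])
  }
  n_tp <- length(pair_t)
  new_match_result(
    pairs = tibble::tibble(truth_row = pair_t, found_row = pair_f,
                           distance = pair_d),
    n_tp = n_tp, n_fp = n_f - n_tp, n_fn = n_t - n_tp,
    jaccard = n_tp / (n_tp + (n_t - n_tp) + (n_f - n_tp)),
    rmse_px = if (n_tp > 0L) sqrt(mean(pair_d^2)) else NA_real_,
    pixel_size_nm = pixel_size_nm, degenerate = FALSE
  )
}

new_match_result <- function(pairs, n_tp, n_fp, n_fn, jaccard, rmse_px,
                             pixel_size_nm, degenerate) {
  structure(
    list(pairs = pairs, n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
         jaccard = jaccard, rmse_px = rmse_px,
         rmse_nm = if (is.finite(pixel_size_nm)) rmse_px * pixel_size_nm
                   else NA_real_,
         degenerate = degenerate),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FP %d, FN %d | Jaccard %.4f | RMSE %.4f px%s\n",
    x$n_tp, x$n_fp, x$n_fn, x$jaccard, x$rmse_px,
    if (is.finite(x$rmse_nm)) sprintf(" (%.2f nm)", x$rmse_nm) else ""
  ))
  invisible(x)
}

normalize_positions <- function(tab) {
  tab <- tibble::as_tibble(tab)
  if (!"x" %in% names(tab) && "mu_x" %in% names(tab)) tab$x <- tab$mu_x
  if (!"y" %in% names(tab) && "mu_y" %in% names(tab)) tab$y <- tab$mu_y
  if (!"frame" %in% names(tab)) tab$frame <- 0
  tab[c("frame", "x", "y")]
}

#' Fourier ring correlation between two localization sets
#'
#' Both sets are binned into 2D histograms at super-resolution pixel size
#' `super_px`; the correlation per radial spatial-frequency ring is
#' `Re<F_A conj(F_B)> / sqrt(<|F_A|^2><|F_B|^2>)`. The resolution is the
#' inverse of the lowest frequency where the curve — smoothed with a
#' 3-ring moving average to suppress spurious single-ring crossings —
#' first drops below `threshold` times its maximum. The conventional
#' threshold is 1/7. For simulation scoring the two sets are the ground
#' truth and the observed localizations; for experimental data use two
#' random halves of one set.
#'
#' @param set_a,set_b data frames with `x`, `y` in px (aliases
#'   `mu_x`/`mu_y` accepted); both non-empty.
#' @param pixel_size_nm camera pixel size (nm) converting px to nm.
#' @param super_px super-resolution bin size in nm.
#' @param field_nm field of view extent in nm; defaults to the joint
#'   bounding box. Must span at least 64 super-pixels.
#' @param threshold crossing threshold relative to the curve maximum.
#' @return An `frc_curve` list: `spatial_frequency` (nm^-1 ring centers),
#'   `correlation`, `smoothed`, `resolution_nm` (`NA` with
#'   `no_crossing = TRUE` when the curve never drops below threshold),
#'   `threshold`.
#' @export
frc_curve <- function(set_a, set_b, pixel_size_nm, super_px = 10,
                      field_nm = NULL, threshold = 1 / 7) {
  a <- normalize_positions(set_a); b <- normalize_positions(set_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("FRC needs two non-empty localization sets", call. = FALSE)
  }
  ax <- a$x * pixel_size_nm; ay <- a$y * pixel_size_nm
  bx <- b$x * pixel_size_nm; by <- b$y * pixel_size_nm
  if (is.null(field_nm)) {
    field_nm <- max(ax, ay, bx, by) * 1.001 + super_px
  }
  n_bins <- ceiling(field_nm / super_px)
  if (n_bins < 64L) {
    stop("field must span at least 64 super-pixels; shrink `super_px`",
         call. = FALSE)
  }
  ha <- bin2d(ax, ay, super_px, n_bins)
  hb <- bin2d(bx, by, super_px, n_bins)
  if (sum(ha) <= 1 || sum(hb) <= 1) {
    return(new_frc_curve(numeric(0), numeric(0), numeric(0), NA_real_,
                         TRUE, threshold))
  }
  fa <- stats::fft(ha)
  fb <- stats::fft(hb)
  num <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  # radial ring index from FFT frequencies
  k <- c(0:(n_bins %/% 2), -((n_bins - n_bins %/% 2 - 1):1))
  kx <- outer(rep(1, n_bins), k)
  ky <- outer(k, rep(1, n_bins))
  ring <- pmin(round(sqrt(kx^2 + ky^2)), n_bins %/% 2) + 1L
  n_rings <- n_bins %/% 2 + 1L
  s_num <- rowsum_by(num, ring, n_rings)
  s_pa <- rowsum_by(pa, ring, n_rings)
  s_pb <- rowsum_by(pb, ring, n_rings)
  corr <- s_num / sqrt(pmax(s_pa * s_pb, .Machine$double.xmin))
  freq <- (seq_len(n_rings) - 1L) / (n_bins * super_px)   # nm^-1
  sm <- smooth3(corr)
  cmax <- max(sm)
  below <- which(sm < threshold * cmax & freq > 0)
  if (length(below) == 0L) {
    return(new_frc_curve(freq, corr, sm, NA_real_, TRUE, threshold))
  }
  # refine the first crossing by linear interpolation between rings
  i <- below[1L]
  f_cross <- if (i > 1L) {
    y0 <- sm[i - 1L]; y1 <- sm[i]; yt <- threshold * cmax
    freq[i - 1L] + (freq[i] - freq[i - 1L]) * (y0 - yt) / (y0 - y1)
  } else {
    freq[i]
  }
  new_frc_curve(freq, corr, sm, 1 / f_cross, FALSE, threshold)
}

new_frc_curve <- function(freq, corr, smoothed, resolution_nm, no_crossing,
                          threshold) {
  structure(
    list(spatial_frequency = freq, correlation = corr, smoothed = smoothed,
         resolution_nm = resolution_nm, no_crossing = no_crossing,
         threshold = threshold),
    class = "frc_curve"
  )
}

#' @export
print.frc_curve <- function(x, ...) {
  if (x$no_crossing) {
    cat("<frc_curve> no threshold crossing (resolution undetermined)\n")
  } else {
    cat(sprintf("<frc_curve> resolution %.1f nm (threshold %.3f)\n",
                x$resolution_nm, x$threshold))
  }
  invisible(x)
}

bin2d <- function(x_nm, y_nm, super_px, n_bins) {
  ix <- pmin(pmax(floor(x_nm / super_px), 0), n_bins - 1L)
  iy <- pmin(pmax(floor(y_nm / super_px), 0), n_bins - 1L)
  m <- matrix(0, n_bins, n_bins)
  tab <- table(iy + n_bins * ix)
  idx <- as.integer(names(tab)) + 1L
  m[idx] <- as.numeric(tab)
  m
}

rowsum_by <- function(values, group, n) {
  out <- numeric(n)
  s <- rowsum(as.vector(values), as.vector(group))
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1L)] <- (v[1:(n - 2L)] + v[2:(n - 1L)] + v[3:n]) / 3
  out[1L] <- (v[1L] + v[2L]) / 2
  out[n] <- (v[n - 1L] + v[n]) / 2
  out
}
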