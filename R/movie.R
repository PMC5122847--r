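#' Movie stacks
#'
#' A `movie_stack` is the raw input of the pipeline: a T x H x W array of
#' camera intensities together with the physical pixel size and, optionally,
#' the camera acquisition time. Intensities are analog-digital converter
#' counts until [convert_to_photons()] has been applied, after which the
#' `unit` field is `"photons"`.
#'
#' @param data numeric array of dimension `c(T, H, W)`, or an `H x W` matrix
#'   for a single-frame movie. All values must be finite.
#' @param pixel_size_nm physical edge length of one camera pixel in nm.
#' @param frame_time_s camera acquisition time per frame in seconds, or `NA`.
#' @param unit `"counts"` or `"photons"`.
#'
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, pixel_size_nm, frame_time_s = NA_real_,
                        unit = c("counts", "photons")) {
  unit <- match.arg(unit)
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a T x H x W array or an H x W matrix", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("movie dimensions must all be >= 1", call. = FALSE)
  if (!all(is.finite(data))) stop("movie intensities must all be finite", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      data = data,
      pixel_size_nm = as.numeric(pixel_size_nm),
      frame_time_s = as.numeric(frame_time_s),
      unit = unit
    ),
    class = "movie_stack"
  )
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' Number of frames in a movie stack
#' @param movie a [movie_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[1L]

#' Extract one frame of a movie as a matrix
#'
#' @param movie a [movie_stack()].
#' @param frame 0-based frame index in `[0, T)`.
#' @return An `H x W` numeric matrix.
#' @export
get_frame <- function(movie, frame) {
  stopifnot(inherits(movie, "movie_stack"))
  t <- n_frames(movie)
  if (frame < 0 || frame >= t) {
    stop(sprintf("frame %d outside [0, %d)", frame, t), call. = FALSE)
  }
  matrix(movie$data[frame + 1L, , ], nrow = dim(movie$data)[2L])
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<movie_stack> %d frame(s) of %d x %d px [%s], pixel %g nm%s\n",
    d[1L], d[2L], d[3L], x$unit, x$pixel_size_nm,
    if (is.finite(x$frame_time_s)) sprintf(", %g s/frame", x$frame_time_s) else ""
  ))
  invisible(x)
}

#' Read a grayscale TIFF movie
#'
#' Reads a single- or multi-page grayscale TIFF into a [movie_stack()].
#' Integer pixel data are preserved losslessly (the file is read `as.is`,
#' without rescaling to `[0, 1]`).
#'
#' @param path path to an existing TIFF file.
#' @param pixel_size_nm physical pixel size in nm (not stored in most
#'   microscopy TIFFs, so it must be supplied).
#' @param frame_time_s optional acquisition time per frame in seconds.
#' @return A [movie_stack()] with `T` equal to the page count.
#' @export
read_movie <- function(path, pixel_size_nm, frame_time_s = NA_real_) {
  if (!file.exists(path)) {
    stop(sprintf("movie file not found: '%s'", path), call. = FALSE)
  }
  # as.is preserves integer data losslessly; float TIFFs reject it and are
  # read natively instead
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L) {
      stop("movie must be grayscale (one channel per page)", call. = FALSE)
    }
  }
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1L)))) {
    stop("TIFF pages have inconsistent shapes", call. = FALSE)
  }
  dat <- array(0, dim = c(length(pages), shp[1L], shp[2L]))
  for (i in seq_along(pages)) dat[i, , ] <- pages[[i]]
  movie_stack(dat, pixel_size_nm = pixel_size_nm, frame_time_s = frame_time_s)
}

#' Write a movie stack to a multi-page 16-bit TIFF
#'
#' Values are rounded to the nearest integer (camera counts and photon
#' draws are integral); the dynamic range must fit 16 bits.
#'
#' @param movie a [movie_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  dat <- round(movie$data)
  if (any(dat < 0) || max(dat) > 65535) {
    stop("movie values outside the 16-bit range [0, 65535]", call. = FALSE)
  }
  t <- dim(dat)[1L]
  pages <- lapply(seq_len(t), function(i) {
    matrix(dat[i, , ], nrow = dim(dat)[2L]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
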