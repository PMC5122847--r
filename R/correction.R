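#' Convert camera counts to photons
#'
#' Stage 1 of the pipeline: subtract the camera offset and (optionally) the
#' dark signal, then divide by the gain to obtain photo-electron counts,
#' which a Poisson maximum-likelihood fit requires. Corrected values below
#' zero are clipped to 0 — a Poisson mean cannot be negative — and the
#' number of clipped pixels is recorded in the `n_clipped` attribute.
#'
#' @param movie a [movie_stack()] in counts.
#' @param gain camera gain in counts per photon (> 0).
#' @param offset camera offset in counts.
#' @param dark optional dark signal: an `H x W` matrix, or a [movie_stack()]
#'   whose pixelwise mean over frames is used.
#' @return A [movie_stack()] in photons, with attribute `n_clipped`.
#' @export
convert_to_photons <- function(movie, gain = 1, offset = 0, dark = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0) {
    stop("`gain` must be a single positive number (counts/photon)", call. = FALSE)
  }
  if (identical(movie$unit, "photons")) {
    warning("movie is already in photons; converting anyway")
  }
  d <- dim(movie$data)
  dark_img <- NULL
  if (!is.null(dark)) {
    if (inherits(dark, "movie_stack")) {
      dark_img <- apply(dark$data, c(2L, 3L), mean)
    } else if (is.matrix(dark)) {
      dark_img <- dark
    } else {
      stop("`dark` must be a matrix or a movie_stack", call. = FALSE)
    }
    if (!identical(dim(dark_img), d[2:3])) {
      stop(sprintf("dark image is %d x %d but movie frames are %d x %d",
                   nrow(dark_img), ncol(dark_img), d[2L], d[3L]), call. = FALSE)
    }
  }
  corrected <- movie$data - offset
  if (!is.null(dark_img)) {
    corrected <- sweep(corrected, c(2L, 3L), dark_img, `-`)
  }
  n_clipped <- sum(corrected < 0)
  corrected[corrected < 0] <- 0
  out <- movie_stack(corrected / gain, pixel_size_nm = movie$pixel_size_nm,
                     frame_time_s = movie$frame_time_s, unit = "photons")
  attr(out, "n_clipped") <- n_clipped
  out
}
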