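#' Run the localization pipeline on a movie
#'
#' Convenience wrapper chaining candidate detection and refinement through
#' the plugin system and packaging the outcome — tables plus the complete
#' plugin/parameter provenance — into a [result_bundle()].
#'
#' @param movie a [movie_stack()] in photon units (see
#'   [convert_to_photons()]).
#' @param detector,refiner names of registered detection/refinement
#'   plugins.
#' @param detector_params,refiner_params named parameter lists; omitted
#'   parameters take their declared defaults. The refiner's
#'   `pixel_size_nm`, when declared, is filled from the movie.
#' @param frames optional integer range of frames to process (0-based,
#'   e.g. `0:49`); the frames are cut out of the movie before processing.
#' @return A [result_bundle()] with `candidates`, `localizations` and
#'   provenance for both stages.
#' @export
locate_movie <- function(movie, detector = "wavelet", refiner = "gauss_mle",
                         detector_params = list(), refiner_params = list(),
                         frames = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!is.null(frames)) {
    frames <- sort(unique(as.integer(frames)))
    stopifnot(all(frames >= 0), all(frames < n_frames(movie)))
    movie <- movie_stack(movie$data[frames + 1L, , , drop = FALSE],
                         movie$pixel_size_nm, movie$frame_time_s, movie$unit)
  }
  det <- get_plugin("detection", detector)
  ref <- get_plugin("refinement", refiner)
  if ("pixel_size_nm" %in% names(ref$params) &&
      !"pixel_size_nm" %in% names(refiner_params)) {
    refiner_params$pixel_size_nm <- movie$pixel_size_nm
  }
  cands <- run_stage(det, movie, detector_params)
  locs <- run_stage(ref, movie, refiner_params, upstream = cands)
  result_bundle(
    candidates = cands,
    localizations = locs,
    provenance = list(
      detection = stage_provenance(det, detector_params),
      refinement = stage_provenance(ref, refiner_params)
    ),
    movie_meta = list(pixel_size_nm = movie$pixel_size_nm,
                      frame_time_s = movie$frame_time_s,
                      n_frames = n_frames(movie),
                      unit = movie$unit)
  )
}

#' Link a bundle's localizations into tracks
#'
#' @param bundle a [result_bundle()] with localizations.
#' @param tracker name of a registered tracking plugin.
#' @param params tracker parameter overrides.
#' @return The bundle with `tracks` filled in and tracking provenance
#'   appended.
#' @export
track_bundle <- function(bundle, tracker = "nearest_neighbor", params = list()) {
  stopifnot(inherits(bundle, "result_bundle"))
  tk <- get_plugin("tracking", tracker)
  bundle$tracks <- run_stage(tk, upstream = bundle$localizations,
                             params = params)
  bundle$provenance$tracking <- stage_provenance(tk, params)
  bundle
}
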