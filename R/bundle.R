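#' Result bundles: tables plus full provenance
#'
#' A `result_bundle` collects the three stage tables with everything needed
#' to re-run the identical analysis: the plugin used at each stage and every
#' parameter value it saw, plus the movie metadata.
#'
#' @param candidates detection-stage [result_table()].
#' @param localizations refinement-stage [result_table()].
#' @param tracks tracking-stage [result_table()].
#' @param provenance named list, one entry per executed stage, each holding
#'   at least `plugin` (name) and `params` (named list of all values).
#' @param movie_meta named list with e.g. `path`, `pixel_size_nm`,
#'   `frame_time_s`, `n_frames`.
#' @return An object of class `result_bundle`.
#' @export
result_bundle <- function(candidates = empty_stage_table("detection"),
                          localizations = empty_stage_table("refinement"),
                          tracks = empty_stage_table("tracking"),
                          provenance = list(),
                          movie_meta = list()) {
  structure(
    list(
      candidates = result_table(candidates, "detection"),
      localizations = result_table(localizations, "refinement"),
      tracks = result_table(tracks, "tracking"),
      provenance = provenance,
      movie_meta = movie_meta
    ),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf(
    "<result_bundle> %d candidate(s), %d localization(s), %d track point(s)\n",
    nrow(x$candidates), nrow(x$localizations), nrow(x$tracks)
  ))
  if (length(x$provenance) > 0L) {
    cat("stages:", paste(names(x$provenance), collapse = " -> "), "\n")
  }
  invisible(x)
}

# doubles go through "%.17g" strings: enough digits to reproduce every
# finite IEEE double exactly, which plain JSON numbers do not guarantee
encode_column <- function(v) {
  if (is.double(v)) {
    list(type = "double", values = sprintf("%.17g", v))
  } else if (is.integer(v)) {
    list(type = "integer", values = v)
  } else if (is.logical(v)) {
    list(type = "logical", values = v)
  } else {
    list(type = "character", values = as.character(v))
  }
}

decode_column <- function(col) {
  v <- unlist(col$values)
  if (length(v) == 0L) {
    v <- switch(col$type, double = numeric(0), integer = integer(0),
                logical = logical(0), character = character(0))
    return(v)
  }
  switch(col$type,
    double = as.numeric(v),
    integer = as.integer(v),
    logical = as.logical(v),
    character = as.character(v)
  )
}

encode_table <- function(x, stage) {
  list(
    stage = stage,
    columns = names(x),
    data = lapply(stats::setNames(names(x), names(x)), function(n) encode_column(x[[n]]))
  )
}

decode_table <- function(enc) {
  cols <- unlist(enc$columns)
  if (is.null(cols)) cols <- character(0)
  vals <- lapply(cols, function(n) decode_column(enc$data[[n]]))
  tab <- tibble::as_tibble(stats::setNames(vals, cols))
  result_table(tab, enc$stage)
}

#' Save / load a result bundle
#'
#' The bundle is persisted as a single hierarchical JSON file: open,
#' language-neutral and self-describing. Doubles are stored as 17-digit
#' strings so the round trip is bit-identical; provenance strings (including
#' any non-ASCII plugin description) are preserved verbatim.
#'
#' @param bundle a [result_bundle()].
#' @param path file path (conventionally `.json`).
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()` the
#'   reconstructed [result_bundle()].
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  doc <- list(
    format = "spotlink-bundle",
    version = 1L,
    tables = list(
      candidates = encode_table(bundle$candidates, "detection"),
      localizations = encode_table(bundle$localizations, "refinement"),
      tracks = encode_table(bundle$tracks, "tracking")
    ),
    provenance = bundle$provenance,
    movie_meta = bundle$movie_meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop(sprintf("bundle not found: '%s'", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "spotlink-bundle")) {
    stop("not a spotlink bundle (missing 'format' marker)", call. = FALSE)
  }
  for (sec in c("tables", "provenance", "movie_meta")) {
    if (is.null(doc[[sec]])) {
      stop(sprintf("corrupt bundle: missing section '%s'", sec), call. = FALSE)
    }
  }
  for (tb in c("candidates", "localizations", "tracks")) {
    if (is.null(doc$tables[[tb]])) {
      stop(sprintf("corrupt bundle: missing table '%s'", tb), call. = FALSE)
    }
  }
  result_bundle(
    candidates = decode_table(doc$tables$candidates),
    localizations = decode_table(doc$tables$localizations),
    tracks = decode_table(doc$tables$tracks),
    provenance = doc$provenance,
    movie_meta = doc$movie_meta
  )
}

#' Export bundle tables as CSV
#'
#' Writes one CSV per non-empty table (`<stem>_candidates.csv`, ...), each
#' with a header row naming the columns.
#'
#' @param bundle a [result_bundle()].
#' @param stem output path stem.
#' @return Character vector of files written, invisibly.
#' @export
export_bundle_csv <- function(bundle, stem) {
  stopifnot(inherits(bundle, "result_bundle"))
  written <- character(0)
  for (nm in c("candidates", "localizations", "tracks")) {
    tab <- bundle[[nm]]
    f <- paste0(stem, "_", nm, ".csv")
    utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
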