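#' Stage result tables
#'
#' Every pipeline stage returns its output as a flat table with one column
#' per output parameter. Each stage has mandatory leading columns:
#'
#' * detection:  `frame`, `x`, `y`
#' * refinement: `frame`, `x`, `y`, `N`, `b`, `sigma_x`
#' * tracking:   `track_id`, `frame`, `x`, `y`
#'
#' Coordinates are 0-based pixel indices: a point at the center of pixel
#' `(row i, column j)` has `x = j`, `y = i`; sub-pixel positions are floats
#' in pixel units and convert to nm by multiplying with the pixel size.
#' Frame indices are 0-based integers in `[0, T)`.
#'
#' @param x a data frame holding the stage output.
#' @param stage `"detection"`, `"refinement"` or `"tracking"`.
#' @param n_frames optional movie length used to validate frame indices.
#' @return A tibble with attribute `stage` set, validated.
#' @export
result_table <- function(x, stage = c("detection", "refinement", "tracking"),
                         n_frames = NULL) {
  stage <- match.arg(stage)
  x <- tibble::as_tibble(x)
  need <- stage_columns(stage)
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("%s table lacks mandatory column(s): %s",
                 stage, paste(missing, collapse = ", ")), call. = FALSE)
  }
  # mandatory columns lead, extras keep their relative order
  x <- x[c(need, setdiff(names(x), need))]
  if (anyNA(x)) stop("result tables must not contain missing values", call. = FALSE)
  if (nrow(x) > 0L) {
    if (any(x$frame != floor(x$frame))) {
      stop("frame indices must be integers", call. = FALSE)
    }
    if (any(x$frame < 0)) stop("frame indices must be >= 0", call. = FALSE)
    if (!is.null(n_frames) && any(x$frame >= n_frames)) {
      stop(sprintf("frame index beyond movie length %d", n_frames), call. = FALSE)
    }
  }
  attr(x, "stage") <- stage
  x
}

stage_columns <- function(stage) {
  switch(stage,
    detection  = c("frame", "x", "y"),
    refinement = c("frame", "x", "y", "N", "b", "sigma_x"),
    tracking   = c("track_id", "frame", "x", "y"),
    stop("unknown stage: ", stage, call. = FALSE)
  )
}

#' @rdname result_table
#' @export
table_stage <- function(x) attr(x, "stage")

empty_stage_table <- function(stage) {
  cols <- stage_columns(stage)
  out <- tibble::as_tibble(stats::setNames(
    replicate(length(cols), numeric(0), simplify = FALSE), cols
  ))
  result_table(out, stage)
}

# stable stage-output ordering: (frame, x, y); makes frame-parallel
# execution order-invariant
sort_stage_table <- function(x, stage) {
  if (nrow(x) > 0L) {
    if (stage == "tracking") {
      x <- x[order(x$track_id, x$frame, x$x, x$y), ]
    } else {
      x <- x[order(x$frame, x$x, x$y), ]
    }
  }
  result_table(x, stage)
}
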