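#' Typed plugin parameters
#'
#' Every plugin declares its inputs as a list of typed parameter specs. The
#' declaration carries enough information (kind, default, range or choices,
#' tooltip) to build the command-line/config interface for the plugin
#' without any further code; the tooltip is mandatory so that an algorithm's
#' knobs are always documented at the point of use.
#'
#' @param name identifier (letters, digits, `_`).
#' @param kind one of `"int"`, `"float"`, `"bool"`, `"string"`, `"list"`,
#'   `"filepath"`.
#' @param default default value, of the given kind.
#' @param range for `int`/`float`: optional `c(min, max)`; for `list`: the
#'   character vector of allowed choices.
#' @param tooltip non-empty explanatory text.
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, kind, default, range = NULL, tooltip) {
  kinds <- c("int", "float", "bool", "string", "list", "filepath")
  if (!kind %in% kinds) stop("unknown parameter kind: ", kind, call. = FALSE)
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", name)) {
    stop("invalid parameter name: ", name, call. = FALSE)
  }
  if (!is.character(tooltip) || length(tooltip) != 1L || !nzchar(trimws(tooltip))) {
    stop(sprintf("parameter '%s' has an empty tooltip; tooltips are mandatory",
                 name), call. = FALSE)
  }
  spec <- structure(
    list(name = name, kind = kind, default = default, range = range,
         tooltip = tooltip),
    class = "param_spec"
  )
  validate_param_value(spec, default, context = "default for")
  spec
}

validate_param_value <- function(spec, value, context = "value of") {
  bad <- function(msg) {
    stop(sprintf("%s parameter '%s' %s", context, spec$name, msg), call. = FALSE)
  }
  switch(spec$kind,
    int = {
      if (!is.numeric(value) || length(value) != 1L || value != floor(value)) {
        bad("must be a single integer")
      }
    },
    float = {
      if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
        bad("must be a single finite number")
      }
    },
    bool = if (!is.logical(value) || length(value) != 1L || is.na(value)) {
      bad("must be TRUE or FALSE")
    },
    string = ,
    filepath = if (!is.character(value) || length(value) != 1L) {
      bad("must be a single string")
    },
    list = {
      if (!is.character(value) || length(value) != 1L) bad("must be a single choice")
      if (!value %in% spec$range) {
        bad(sprintf("must be one of {%s}, got '%s'",
                    paste(spec$range, collapse = ", "), value))
      }
    }
  )
  if (spec$kind %in% c("int", "float") && !is.null(spec$range)) {
    if (value < spec$range[1L] || value > spec$range[2L]) {
      bad(sprintf("= %g outside range [%g, %g]", value,
                  spec$range[1L], spec$range[2L]))
    }
  }
  invisible(TRUE)
}

#' Plugin descriptors
#'
#' A plugin is one descriptor object: its name, the pipeline stage it
#' serves, a mandatory description, its typed parameter list, and the
#' entry point. Detection and refinement plugins declare
#' `frame_independent = TRUE` and their `main` is called once per frame
#' (`main(frame_image, frame_index, params)` for detection,
#' `main(frame_image, frame_index, candidates, params)` for refinement);
#' tracking plugins operate on the whole localization list at once
#' (`main(localizations, params)`).
#'
#' @param name plugin identifier, unique within its stage.
#' @param stage `"detection"`, `"refinement"` or `"tracking"`.
#' @param description non-empty text describing the algorithm.
#' @param params list of [param_spec()]s.
#' @param main the entry-point function (see Details).
#' @param frame_independent whether frames can be processed in any order
#'   or concurrently. Must be `FALSE` for tracking.
#' @return A `plugin_descriptor` object.
#' @export
plugin_descriptor <- function(name, stage, description, params, main,
                              frame_independent = stage != "tracking") {
  stage <- match.arg(stage, c("detection", "refinement", "tracking"))
  if (!is.character(description) || !nzchar(trimws(description))) {
    stop("plugin description is mandatory and must be non-empty", call. = FALSE)
  }
  stopifnot(is.function(main))
  if (!all(vapply(params, inherits, logical(1L), "param_spec"))) {
    stop("`params` must be a list of param_spec objects", call. = FALSE)
  }
  pnames <- vapply(params, `[[`, character(1L), "name")
  if (anyDuplicated(pnames)) {
    stop("duplicate parameter names in plugin '", name, "'", call. = FALSE)
  }
  if (stage == "tracking" && frame_independent) {
    stop("tracking plugins consume temporal information; frame_independent must be FALSE",
         call. = FALSE)
  }
  structure(
    list(name = name, stage = stage, description = description,
         params = stats::setNames(params, pnames), main = main,
         frame_independent = frame_independent),
    class = "plugin_descriptor"
  )
}

the_registry <- new.env(parent = emptyenv())

#' Plugin registry
#'
#' Plugins are discoverable by `(stage, name)`. Built-in plugins are
#' registered when the package loads; users add their own with
#' `register_plugin()`.
#'
#' @param descriptor a [plugin_descriptor()].
#' @param overwrite replace an existing plugin of the same stage and name.
#' @return `register_plugin()` the descriptor invisibly; `get_plugin()` a
#'   descriptor; `list_plugins()` a tibble of name, stage, description and
#'   parameter count.
#' @export
register_plugin <- function(descriptor, overwrite = FALSE) {
  stopifnot(inherits(descriptor, "plugin_descriptor"))
  key <- paste(descriptor$stage, descriptor$name, sep = "/")
  if (!overwrite && !is.null(the_registry[[key]])) {
    stop(sprintf("a %s plugin named '%s' is already registered",
                 descriptor$stage, descriptor$name), call. = FALSE)
  }
  the_registry[[key]] <- descriptor
  invisible(descriptor)
}

#' @rdname register_plugin
#' @param stage,name plugin lookup key.
#' @export
get_plugin <- function(stage, name) {
  key <- paste(stage, name, sep = "/")
  pl <- the_registry[[key]]
  if (is.null(pl)) {
    stop(sprintf("no %s plugin named '%s' is registered", stage, name),
         call. = FALSE)
  }
  pl
}

#' @rdname register_plugin
#' @export
list_plugins <- function() {
  keys <- sort(ls(the_registry))
  rows <- lapply(keys, function(k) {
    p <- the_registry[[k]]
    tibble::tibble(stage = p$stage, name = p$name,
                   description = p$description,
                   n_params = length(p$params))
  })
  dplyr::bind_rows(rows)
}

#' Auto-generate the command-line/config schema of a plugin
#'
#' One flag per declared parameter, carrying kind, default, range/choices
#' and the tooltip as help text. The schema is exhaustive by construction:
#' it is derived from the descriptor, so a parameter cannot be missed.
#'
#' @param descriptor a [plugin_descriptor()].
#' @return A tibble with columns `flag`, `name`, `kind`, `default`,
#'   `range`, `help`.
#' @export
build_cli_schema <- function(descriptor) {
  stopifnot(inherits(descriptor, "plugin_descriptor"))
  rows <- lapply(descriptor$params, function(p) {
    rng <- if (is.null(p$range)) {
      NA_character_
    } else if (p$kind == "list") {
      paste(p$range, collapse = "|")
    } else {
      sprintf("[%g, %g]", p$range[1L], p$range[2L])
    }
    tibble::tibble(
      flag = paste0("--", gsub("_", "-", p$name)),
      name = p$name,
      kind = p$kind,
      default = format(p$default),
      range = rng,
      help = p$tooltip
    )
  })
  dplyr::bind_rows(rows)
}

#' Parse and validate parameter values against a plugin's specs
#'
#' Missing parameters take their declared default; values are coerced from
#' strings (as arriving from a CLI or config file) according to the
#' declared kind, then validated against range/choices.
#'
#' @param descriptor a [plugin_descriptor()].
#' @param values named list of supplied values (possibly strings).
#' @return Named list with one validated value per declared parameter.
#' @export
resolve_params <- function(descriptor, values = list()) {
  unknown <- setdiff(names(values), names(descriptor$params))
  if (length(unknown) > 0L) {
    stop(sprintf("plugin '%s' has no parameter(s): %s", descriptor$name,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(descriptor$params, function(p) {
    v <- if (p$name %in% names(values)) values[[p$name]] else p$default
    if (is.character(v) && p$kind %in% c("int", "float", "bool")) {
      v <- switch(p$kind,
        int = suppressWarnings(as.integer(v)),
        float = suppressWarnings(as.numeric(v)),
        bool = as.logical(toupper(v))
      )
      if (is.na(v)) {
        stop(sprintf("cannot parse value for parameter '%s'", p$name),
             call. = FALSE)
      }
    }
    if (p$kind == "int") v <- as.integer(v)
    validate_param_value(p, v)
    v
  })
  stats::setNames(out, names(descriptor$params))
}

#' Execute one pipeline stage through a plugin
#'
#' Detection and refinement plugins are applied frame by frame. When the
#' plugin declares `frame_independent = TRUE` the frames may be processed
#' in any order (the `frame_order` argument exists to exercise this
#' contract); the result is always returned sorted by `(frame, x, y)`, so
#' the output is identical whether frames ran sequentially, reversed, or
#' concurrently. Tracking plugins run exactly once over the whole
#' localization table.
#'
#' @param descriptor a [plugin_descriptor()].
#' @param movie a [movie_stack()] (may be `NULL` for tracking).
#' @param params named list of parameter values (defaults filled in).
#' @param upstream upstream [result_table()]: candidates for refinement,
#'   localizations for tracking; `NULL` for detection.
#' @param frame_order optional permutation of `0:(T-1)` fixing the
#'   processing order for frame-independent plugins.
#' @return A [result_table()] for the descriptor's stage.
#' @export
run_stage <- function(descriptor, movie = NULL, params = list(),
                      upstream = NULL, frame_order = NULL) {
  stopifnot(inherits(descriptor, "plugin_descriptor"))
  params <- resolve_params(descriptor, params)
  stage <- descriptor$stage

  if (stage == "tracking") {
    if (is.null(upstream)) {
      stop("tracking requires an upstream localization table", call. = FALSE)
    }
    out <- descriptor$main(upstream, params)
    return(sort_stage_table(result_table(out, "tracking"), "tracking"))
  }

  stopifnot(inherits(movie, "movie_stack"))
  t <- n_frames(movie)
  if (is.null(frame_order)) {
    frame_order <- 0:(t - 1L)
  } else {
    if (!setequal(frame_order, 0:(t - 1L))) {
      stop("`frame_order` must be a permutation of all frame indices", call. = FALSE)
    }
    if (!descriptor$frame_independent) {
      stop(sprintf("plugin '%s' requires temporal order; frames cannot be permuted",
                   descriptor$name), call. = FALSE)
    }
  }
  if (stage == "refinement" && is.null(upstream)) {
    stop("refinement requires an upstream candidate table", call. = FALSE)
  }

  pieces <- vector("list", t)
  for (f in frame_order) {
    frame_img <- get_frame(movie, f)
    res <- tryCatch(
      {
        if (stage == "detection") {
          descriptor$main(frame_img, f, params)
        } else {
          cand_f <- upstream[upstream$frame == f, , drop = FALSE]
          descriptor$main(frame_img, f, cand_f, params)
        }
      },
      error = function(e) {
        stop(sprintf("plugin '%s' failed on frame %d: %s",
                     descriptor$name, f, conditionMessage(e)), call. = FALSE)
      }
    )
    pieces[[f + 1L]] <- tibble::as_tibble(res)
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) out <- empty_stage_table(stage)
  sort_stage_table(result_table(out, stage, n_frames = t), stage)
}

stage_provenance <- function(descriptor, params) {
  list(plugin = descriptor$name, stage = descriptor$stage,
       params = resolve_params(descriptor, params))
}
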