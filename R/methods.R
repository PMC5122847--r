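#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for evaluation and diffusion results
#'
#' `tidy()` returns the per-element detail (matched pairs, FRC rings, MSD
#' lags) as a tibble; `glance()` the one-row summary.
#'
#' @param x a `match_result`, `frc_curve` or `diffusion_fit`.
#' @param ... unused.
#' @return A tibble.
#' @name spotlink-tidiers
NULL

#' @rdname spotlink-tidiers
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @rdname spotlink-tidiers
#' @method glance match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(n_tp = x$n_tp, n_fp = x$n_fp, n_fn = x$n_fn,
                 jaccard = x$jaccard, rmse_px = x$rmse_px,
                 rmse_nm = x$rmse_nm, degenerate = x$degenerate)
}

#' @rdname spotlink-tidiers
#' @method tidy frc_curve
#' @export
tidy.frc_curve <- function(x, ...) {
  tibble::tibble(spatial_frequency = x$spatial_frequency,
                 correlation = x$correlation, smoothed = x$smoothed)
}

#' @rdname spotlink-tidiers
#' @method glance frc_curve
#' @export
glance.frc_curve <- function(x, ...) {
  tibble::tibble(resolution_nm = x$resolution_nm,
                 no_crossing = x$no_crossing, threshold = x$threshold)
}

#' @rdname spotlink-tidiers
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) x$lags

#' @rdname spotlink-tidiers
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D_um2_s = x$D_um2_s, epsilon_um2 = x$epsilon_um2,
                 D_stderr = x$D_stderr, n_lags = nrow(x$lags),
                 negative_D = x$negative_D)
}

#' Plot an FRC curve
#'
#' Correlation against spatial frequency with the threshold level and, if
#' crossed, the resolution marked.
#'
#' @param object an `frc_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot frc_curve
#' @export
autoplot.frc_curve <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$spatial_frequency)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$correlation), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::geom_hline(yintercept = object$threshold * max(object$smoothed),
                        linetype = "dashed") +
    ggplot2::labs(x = "spatial frequency (1/nm)", y = "ring correlation")
  if (!object$no_crossing) {
    p <- p + ggplot2::geom_vline(xintercept = 1 / object$resolution_nm,
                                 linetype = "dotted") +
      ggplot2::ggtitle(sprintf("FRC resolution %.1f nm", object$resolution_nm))
  }
  p
}

#' Plot a mean-squared-displacement fit
#'
#' Per-lag displacement variance against lag time with the fitted line
#' `sigma^2 = 2 D t + epsilon`.
#'
#' @param object a `diffusion_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot diffusion_fit
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_time_s, y = .data$sigma2_um2)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 2 * object$D_um2_s,
                         intercept = object$epsilon_um2, colour = "red") +
    ggplot2::labs(
      x = "lag time (s)", y = expression(sigma^2 ~ (mu * m^2)),
      title = sprintf("D = %.3g um^2/s, epsilon = %.2g um^2",
                      object$D_um2_s, object$epsilon_um2)
    )
}

#' Overlay stage output on a movie frame
#'
#' Renders one frame as a grey raster with candidates, localizations or
#' track points drawn on top — the static counterpart of an interactive
#' result inspector.
#'
#' @param movie a [movie_stack()].
#' @param table a stage [result_table()] (any stage).
#' @param frame 0-based frame to show.
#' @return A ggplot object.
#' @export
plot_frame_overlay <- function(movie, table, frame = 0L) {
  img <- get_frame(movie, frame)
  df <- tidyr::expand_grid(y = 0:(nrow(img) - 1L), x = 0:(ncol(img) - 1L))
  df$value <- as.vector(t(img))
  pts <- tibble::as_tibble(table)
  pts <- pts[pts$frame == frame, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = pts, colour = "red", shape = 1, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "photons")
}
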