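#' @name builtin-plugins
#' @title Built-in pipeline plugins
#'
#' @description
#' The package ships three detection plugins (`bandpass`, `crosscorr`,
#' `wavelet`), two refinement plugins (`gauss_mle`, `radial_symmetry`)
#' and one tracking plugin (`nearest_neighbor`). They are registered when
#' the package loads; `list_plugins()` enumerates them and
#' `build_cli_schema()` exposes their parameters as command-line flags.
NULL

builtin_detection_common <- function() {
  list(
    param_spec("threshold", "float", -1,
               tooltip = paste("Strict lower score bound for candidate maxima;",
                               "-1 uses the filter's own threshold rule",
                               "(wavelet only)")),
    param_spec("min_distance", "float", 3, range = c(1, 1e3),
               tooltip = "Minimum separation between candidates in px"),
    param_spec("exclude_border", "int", 5L, range = c(0, 1e3),
               tooltip = paste("Drop candidates within this margin of the",
                               "frame edge so a refinement window fits"))
  )
}

detect_with <- function(score_fun) {
  function(frame_img, f, params) {
    sc <- score_fun(frame_img, params)
    thr <- if (params$threshold < 0) NULL else params$threshold
    find_candidates(sc, threshold = thr,
                    min_distance = params$min_distance,
                    exclude_border = params$exclude_border, frame = f)
  }
}

builtin_plugins <- function() {
  list(
    plugin_descriptor(
      name = "bandpass", stage = "detection",
      description = paste("Difference-of-Gaussians band-pass filter:",
                          "small-scale minus large-scale smoothing,",
                          "removing both noise and slowly varying background"),
      params = c(list(
        param_spec("feature_size", "float", 1, range = c(0.1, 50),
                   tooltip = "Sigma (px) of the small-scale smoothing, ~spot size"),
        param_spec("background_size", "float", 4, range = c(0.2, 200),
                   tooltip = "Sigma (px) of the background smoothing, > feature_size")
      ), builtin_detection_common()),
      main = detect_with(function(img, p) {
        bandpass_filter(img, p$feature_size, p$background_size)
      })
    ),
    plugin_descriptor(
      name = "crosscorr", stage = "detection",
      description = paste("Normalized cross-correlation of each window",
                          "against a pixel-integrated Gaussian PSF template;",
                          "scores in [-1, 1], invariant to additive offsets"),
      params = c(list(
        param_spec("sigma_psf", "float", 1.3, range = c(0.3, 10),
                   tooltip = "PSF standard deviation of the template (px)"),
        param_spec("window", "int", 9L, range = c(3, 101),
                   tooltip = "Odd template edge length in px")
      ), builtin_detection_common()),
      main = detect_with(function(img, p) {
        crosscorr_score(img, p$sigma_psf, p$window)
      })
    ),
    plugin_descriptor(
      name = "wavelet", stage = "detection",
      description = paste("A-trous B3-spline wavelet filter; the 2nd detail",
                          "plane isolates spot-scale structure and the",
                          "threshold follows the finest plane's noise level"),
      params = c(list(
        param_spec("levels", "int", 3L, range = c(2, 6),
                   tooltip = "Number of wavelet decomposition levels"),
        param_spec("k_sigma", "float", 2, range = c(0.1, 20),
                   tooltip = "Threshold multiplier on the robust noise std")
      ), builtin_detection_common()),
      main = detect_with(function(img, p) {
        wavelet_filter(img, p$levels, p$k_sigma)
      })
    ),
    plugin_descriptor(
      name = "gauss_mle", stage = "refinement",
      description = paste("Poisson maximum-likelihood fit of a",
                          "pixel-integrated Gaussian PSF (isotropic or",
                          "rotated astigmatic) with CRLB localization",
                          "precision; requires photon units"),
      params = list(
        param_spec("window", "int", 11L, range = c(5, 101),
                   tooltip = "Odd fitting window edge length (px)"),
        param_spec("model", "list", "isotropic",
                   range = c("isotropic", "astigmatic"),
                   tooltip = "PSF model: single width, or two widths plus rotation"),
        param_spec("sigma_init", "float", 1.3, range = c(0.3, 10),
                   tooltip = "Initial PSF width (px), e.g. from the optics"),
        param_spec("max_iter", "int", 100L, range = c(1, 10000),
                   tooltip = "Iteration cap of the optimizer"),
        param_spec("tol", "float", 1e-6, range = c(1e-12, 1e-2),
                   tooltip = "Relative parameter-change convergence threshold"),
        param_spec("pixel_size_nm", "float", 100, range = c(1, 1e4),
                   tooltip = "Pixel size (nm) used to express precision in nm")
      ),
      main = function(frame_img, f, cands, params) {
        if (nrow(cands) == 0L) return(NULL)
        rows <- lapply(seq_len(nrow(cands)), function(i) {
          fit_mle(frame_img, c(cands$x[i], cands$y[i]),
                  window = params$window, model = params$model,
                  sigma_init = params$sigma_init,
                  max_iter = params$max_iter, tol = params$tol,
                  pixel_size_nm = params$pixel_size_nm)
        })
        out <- dplyr::bind_rows(rows)
        out <- out[out$converged & !out$at_bound &
                     stats::complete.cases(out), , drop = FALSE]
        if (nrow(out) == 0L) return(NULL)
        out$frame <- f
        out
      }
    ),
    plugin_descriptor(
      name = "radial_symmetry", stage = "refinement",
      description = paste("Closed-form radial-symmetry center finding from",
                          "image gradients; fast, needs no photon",
                          "calibration; photometry columns are moment",
                          "estimates"),
      params = list(
        param_spec("window", "int", 11L, range = c(3, 101),
                   tooltip = "Odd window edge length around each candidate (px)")
      ),
      main = function(frame_img, f, cands, params) {
        if (nrow(cands) == 0L) return(NULL)
        w <- as.integer(params$window)
        if (w %% 2L == 0L) w <- w + 1L
        r <- w %/% 2L
        h <- nrow(frame_img); wid <- ncol(frame_img)
        rows <- lapply(seq_len(nrow(cands)), function(i) {
          cx <- round(cands$x[i]); cy <- round(cands$y[i])
          if (cx - r < 0 || cx + r > wid - 1L || cy - r < 0 || cy + r > h - 1L) {
            return(NULL)
          }
          win <- frame_img[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L]
          ctr <- radial_symmetry_center(win)
          # moment-based photometry so the refinement table is complete
          b <- stats::median(c(win[1L, ], win[w, ], win[, 1L], win[, w]))
          sig <- pmax(win - b, 0)
          tot <- sum(sig)
          sigma <- if (tot > 0) {
            xs <- 0:(w - 1L)
            mx <- sum(t(sig) * xs) / tot; my <- sum(sig * xs) / tot
            sqrt(max(0.01, (sum(t(sig) * (xs - mx)^2) +
                              sum(sig * (xs - my)^2)) / (2 * tot)))
          } else 1
          tibble::tibble(
            frame = f,
            x = cx - r + ctr$x, y = cy - r + ctr$y,
            N = tot, b = b, sigma_x = sigma,
            flagged = ctr$flagged
          )
        })
        dplyr::bind_rows(rows)
      }
    ),
    plugin_descriptor(
      name = "nearest_neighbor", stage = "tracking",
      description = paste("Frame-to-frame minimum-total-distance optimal",
                          "assignment linker with sqrt(gap)-scaled gap",
                          "closing and minimum track length filtering"),
      params = list(
        param_spec("max_dist", "float", 5, range = c(1e-6, 1e4),
                   tooltip = "Maximum linking distance per frame step (px)"),
        param_spec("max_gap", "int", 0L, range = c(0, 1000),
                   tooltip = "Frames a track survives without a localization"),
        param_spec("min_length", "int", 1L, range = c(1, 1e6),
                   tooltip = "Minimum number of points for a track to be kept")
      ),
      main = function(locs, params) {
        link_nearest_neighbor(locs, max_dist = params$max_dist,
                              max_gap = params$max_gap,
                              min_length = params$min_length)
      },
      frame_independent = FALSE
    )
  )
}

register_builtin_plugins <- function() {
  for (pl in builtin_plugins()) register_plugin(pl, overwrite = TRUE)
  invisible(NULL)
}
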