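#' @name mle-fitting
#' @title Poisson maximum-likelihood spot refinement
#'
#' @description
#' Each candidate is refined by minimizing the Poisson negative
#' log-likelihood `sum(mu - y log mu)` of the pixel-integrated Gaussian
#' model over a square window around the candidate pixel. Optimization is
#' a Levenberg-damped Fisher-scoring (Gauss-Newton) iteration; positivity
#' of `N`, `b` and the widths is kept by fitting their logarithms, so no
#' constrained-solver machinery is needed. A step is accepted only if the
#' cost decreases, hence the cost is non-increasing across accepted
#' iterations. Localization precision is the Cramer-Rao lower bound of the
#' same model evaluated at the fitted parameters.
NULL

# model + Jacobian in natural parameters for the isotropic model
# theta = (mu_x, mu_y, N, b, sigma); returns mu (vector over window pixels)
# and the n_px x 5 Jacobian
iso_model_jac <- function(xs, ys, p) {
  mu_x <- p[1L]; mu_y <- p[2L]; N <- p[3L]; b <- p[4L]; sg <- p[5L]
  dx <- xs - mu_x; dy <- ys - mu_y
  ex <- pixel_erf(dx, sg); ey <- pixel_erf(dy, sg)
  # d(pixel_erf)/d(mu) and d/d(sigma)
  dphi <- function(d) stats::dnorm((d + 0.5) / sg) - stats::dnorm((d - 0.5) / sg)
  dzph <- function(d) {
    (d + 0.5) * stats::dnorm((d + 0.5) / sg) - (d - 0.5) * stats::dnorm((d - 0.5) / sg)
  }
  dex_dmu <- -dphi(dx) / sg
  dey_dmu <- -dphi(dy) / sg
  dex_dsg <- -dzph(dx) / sg^2
  dey_dsg <- -dzph(dy) / sg^2
  EX <- outer(rep(1, length(ys)), ex); EY <- outer(ey, rep(1, length(xs)))
  mu <- N * EX * EY + b
  J <- cbind(
    as.vector(N * outer(ey, dex_dmu)),            # d/d mu_x
    as.vector(N * outer(dey_dmu, ex)),            # d/d mu_y
    as.vector(EX * EY),                           # d/d N
    1,                                            # d/d b
    as.vector(N * (outer(ey, dex_dsg) + outer(dey_dsg, ex)))  # d/d sigma
  )
  list(mu = as.vector(mu), J = J)
}

# astigmatic model: theta = (mu_x, mu_y, N, b, sigma_x, sigma_y, theta);
# Jacobian by central differences (few astigmatic fits, clarity over speed)
ast_model <- function(xs, ys, p) {
  as.vector(integrated_gaussian_model(xs, ys, p[1L], p[2L], p[3L], p[4L],
                                      p[5L], p[6L], p[7L]))
}

ast_model_jac <- function(xs, ys, p) {
  mu <- ast_model(xs, ys, p)
  J <- matrix(0, length(mu), length(p))
  hs <- pmax(1e-6, abs(p) * 1e-6)
  for (i in seq_along(p)) {
    pp <- p; pm <- p
    pp[i] <- p[i] + hs[i]; pm[i] <- p[i] - hs[i]
    J[, i] <- (ast_model(xs, ys, pp) - ast_model(xs, ys, pm)) / (2 * hs[i])
  }
  list(mu = mu, J = J)
}

poisson_nll <- function(mu, y) {
  mu <- pmax(mu, 1e-12)
  sum(mu - y * log(mu))
}

# Levenberg-damped Fisher scoring on transformed parameters.
# `log_idx` marks parameters fitted in log-space; `lower`/`upper` are
# optional box constraints applied by projection after each step (position
# stays inside the window, widths stay physical).
lm_poisson_fit <- function(y, xs, ys, p0, model_jac, log_idx,
                           max_iter = 100L, tol = 1e-6,
                           lower = NULL, upper = NULL) {
  clamp <- function(p) {
    if (!is.null(lower)) p <- pmax(p, lower)
    if (!is.null(upper)) p <- pmin(p, upper)
    p
  }
  p <- clamp(p0)
  lambda <- 1e-3
  mj <- model_jac(xs, ys, p)
  nll <- poisson_nll(mj$mu, y)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu <- pmax(mj$mu, 1e-12)
    J <- mj$J
    # chain rule for log-fitted parameters
    Jt <- J
    for (i in log_idx) Jt[, i] <- J[, i] * p[i]
    w <- 1 / mu
    g <- as.vector(crossprod(Jt, (1 - y / mu)))
    FI <- crossprod(Jt * sqrt(w))
    step_ok <- FALSE
    for (k in 1:12) {
      A <- FI + lambda * diag(pmax(diag(FI), 1e-12), nrow(FI))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        delta <- pmin(pmax(delta, -4), 4)   # trust region on the step
        pn <- p
        for (i in seq_along(p)) {
          pn[i] <- if (i %in% log_idx) p[i] * exp(delta[i]) else p[i] + delta[i]
        }
        pn <- clamp(pn)
        mj_n <- model_jac(xs, ys, pn)
        nll_n <- poisson_nll(mj_n$mu, y)
        if (is.finite(nll_n) && nll_n <= nll) {
          # effective change after projection onto the bounds
          eff <- pn - p
          for (i in log_idx) eff[i] <- log(pn[i] / p[i])
          rel <- max(abs(eff))
          p <- pn; mj <- mj_n
          improved <- nll - nll_n
          nll <- nll_n
          lambda <- max(lambda / 5, 1e-9)
          step_ok <- TRUE
          # stop on parameter stability or cost stagnation
          if (rel < tol || improved < 1e-9 * (abs(nll) + 1)) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) {           # no decreasing step found: local optimum
      converged <- TRUE
      break
    }
    if (converged) break
  }
  list(p = p, nll = nll, converged = converged, n_iter = iter)
}

#' Fit one spot by Poisson maximum likelihood
#'
#' @param frame photon-unit image matrix.
#' @param candidate numeric `c(x, y)` integer-pixel candidate position
#'   (0-based).
#' @param window odd fitting window edge length (px); must fit in the frame.
#' @param model `"isotropic"` (sigma_y = sigma_x, theta = 0) or
#'   `"astigmatic"` (independent widths plus rotation).
#' @param sigma_init initial PSF width in px (e.g. from
#'   [psf_sigma_from_optics()]).
#' @param sigma_bounds allowed `c(min, max)` for the fitted width(s), in
#'   px; the default brackets `sigma_init` generously while excluding the
#'   sub-pixel width collapse of dim-spot fits.
#' @param init optional named list overriding initial values (`mu_x`,
#'   `mu_y`, `N`, `b`, `sigma_x`, `sigma_y`, `theta`).
#' @param max_iter,tol optimizer limits: iteration cap and relative
#'   parameter-change convergence threshold.
#' @param pixel_size_nm pixel size used to express the CRLB precision in
#'   nm; `NA` skips the precision computation.
#' @return One-row tibble with `x`, `y`, `N`, `b`, `sigma_x`, `sigma_y`,
#'   `theta`, `sbr`, `precision_x`, `precision_y` (nm), `converged`,
#'   `n_iter`, `nll`.
#' @export
fit_mle <- function(frame, candidate, window = 11L,
                    model = c("isotropic", "astigmatic"),
                    sigma_init = 1.3, init = list(),
                    sigma_bounds = sigma_init * c(0.5, 3),
                    max_iter = 100L, tol = 1e-6, pixel_size_nm = NA_real_) {
  model <- match.arg(model)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  r <- window %/% 2L
  cx <- round(candidate[1L]); cy <- round(candidate[2L])
  h <- nrow(frame); w <- ncol(frame)
  if (cx - r < 0 || cx + r > w - 1L || cy - r < 0 || cy + r > h - 1L) {
    stop("fit window does not fit inside the frame around the candidate",
         call. = FALSE)
  }
  xs <- (cx - r):(cx + r)
  ys <- (cy - r):(cy + r)
  win <- frame[ys + 1L, xs + 1L, drop = FALSE]
  y <- as.vector(win)

  failed <- function() tibble::tibble(
    x = NA_real_, y = NA_real_, N = NA_real_, b = NA_real_,
    sigma_x = NA_real_, sigma_y = NA_real_, theta = NA_real_,
    sbr = NA_real_, precision_x = NA_real_, precision_y = NA_real_,
    converged = FALSE, at_bound = TRUE, n_iter = 0L, nll = NA_real_
  )
  if (all(y <= 0)) return(failed())

  border <- c(win[1L, ], win[window, ], win[, 1L], win[, window])
  b0 <- max(stats::median(border), 0.01)
  N0 <- max(sum(win) - b0 * window^2, 1)
  p0 <- c(mu_x = cx, mu_y = cy, N = N0, b = b0,
          sigma_x = sigma_init, sigma_y = sigma_init, theta = 0)
  for (nm in names(init)) p0[nm] <- init[[nm]]

  # guardrails: the position stays inside the fit window and the width
  # stays physical (an in-focus PSF narrower than ~half a pixel is a noise
  # artifact, the classic collapse mode of dim-spot MLE)
  slo <- sigma_bounds[1L]; shi <- sigma_bounds[2L]
  if (model == "isotropic") {
    fit <- lm_poisson_fit(y, xs, ys, unname(p0[1:5]), iso_model_jac,
                          log_idx = 3:5, max_iter = max_iter, tol = tol,
                          lower = c(cx - r, cy - r, 1e-3, 1e-9, slo),
                          upper = c(cx + r, cy + r, Inf, Inf, shi))
    p <- c(fit$p, fit$p[5L], 0)   # sigma_y = sigma_x, theta = 0
  } else {
    fit <- lm_poisson_fit(y, xs, ys, unname(p0), ast_model_jac,
                          log_idx = 3:6, max_iter = max_iter, tol = tol,
                          lower = c(cx - r, cy - r, 1e-3, 1e-9, slo, slo, -Inf),
                          upper = c(cx + r, cy + r, Inf, Inf, shi, shi, Inf))
    p <- canonicalize_astigmatic(fit$p)
  }

  sbr <- spot_sbr(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L], p[7L])
  # a solution pinned at a box bound (position at the window edge, width at
  # its physical limit, or no signal left) is not an interior ML optimum;
  # flag it so downstream stages can discard it
  eps <- 1e-6
  at_bound <- abs(p[1L] - (cx - r)) < eps || abs(p[1L] - (cx + r)) < eps ||
    abs(p[2L] - (cy - r)) < eps || abs(p[2L] - (cy + r)) < eps ||
    p[3L] <= 1e-3 * (1 + eps) ||
    abs(p[5L] - sigma_bounds[1L]) < eps || abs(p[5L] - sigma_bounds[2L]) < eps ||
    (model == "astigmatic" &&
       (abs(p[6L] - sigma_bounds[1L]) < eps ||
          abs(p[6L] - sigma_bounds[2L]) < eps))
  prec <- c(NA_real_, NA_real_)
  if (fit$converged && !at_bound && p[3L] > 0 && is.finite(pixel_size_nm)) {
    prec <- crlb_precision_px(p, window, model) * pixel_size_nm
  }
  tibble::tibble(
    x = p[1L], y = p[2L], N = p[3L], b = p[4L],
    sigma_x = p[5L], sigma_y = p[6L], theta = p[7L],
    sbr = sbr,
    precision_x = prec[1L], precision_y = prec[2L],
    converged = fit$converged, at_bound = at_bound,
    n_iter = fit$n_iter, nll = fit$nll
  )
}

# the rotated model is invariant under theta + pi and under swapping the
# widths with theta + pi/2; report the representative with theta in
# (-pi/4, pi/4]
canonicalize_astigmatic <- function(p) {
  th <- ((p[7L] + pi / 2) %% pi) - pi / 2
  if (th > pi / 4 || th <= -pi / 4) {
    p[5:6] <- p[6:5]
    th <- th + if (th > 0) -pi / 2 else pi / 2
  }
  p[7L] <- th
  p
}

# signal-to-background ratio: expected signal density in the pixel holding
# the fitted position, over the fitted background
spot_sbr <- function(mu_x, mu_y, N, b, sigma_x, sigma_y, theta) {
  if (!is.finite(b) || b <= 0) return(Inf)
  px <- round(mu_x); py <- round(mu_y)
  peak <- integrated_gaussian_model(px, py, mu_x, mu_y, N, 0,
                                    sigma_x, sigma_y, theta)
  as.numeric(peak) / b
}

# CRLB of the position estimates, in px, from the Fisher information of the
# fitted model over the same window geometry (window centered at the fitted
# pixel); parameters in natural scale
crlb_precision_px <- function(p, window, model = "isotropic") {
  r <- window %/% 2L
  cx <- round(p[1L]); cy <- round(p[2L])
  xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
  mj <- if (model == "isotropic") {
    iso_model_jac(xs, ys, p[1:5])
  } else {
    ast_model_jac(xs, ys, p)
  }
  mu <- pmax(mj$mu, 1e-12)
  FI <- crossprod(mj$J * sqrt(1 / mu))
  V <- tryCatch(solve(FI), error = function(e) NULL)
  if (is.null(V) || any(diag(V)[1:2] <= 0)) return(c(NA_real_, NA_real_))
  sqrt(diag(V)[1:2])
}

#' Theoretical localization precision of a fitted spot
#'
#' Per-axis standard error of the position estimate from the Fisher
#' information (Cramer-Rao lower bound) of the pixel-integrated Gaussian
#' model at the fitted parameters.
#'
#' @param loc one-row data frame as returned by [fit_mle()] (needs `x`,
#'   `y`, `N`, `b`, `sigma_x`, and `converged`).
#' @param pixel_size_nm pixel size in nm.
#' @param window window edge length (px) the fit used.
#' @return Named numeric `c(precision_x, precision_y)` in nm.
#' @export
localization_precision <- function(loc, pixel_size_nm, window = 11L) {
  if (!isTRUE(loc$converged[1L])) {
    stop("localization precision requires a converged fit", call. = FALSE)
  }
  if (loc$N[1L] <= 0) stop("precision undefined for N <= 0", call. = FALSE)
  model <- if (!is.null(loc$theta) && (loc$theta[1L] != 0 ||
                                       loc$sigma_y[1L] != loc$sigma_x[1L])) {
    "astigmatic"
  } else {
    "isotropic"
  }
  p <- c(loc$x[1L], loc$y[1L], loc$N[1L], loc$b[1L], loc$sigma_x[1L],
         if (model == "astigmatic") c(loc$sigma_y[1L], loc$theta[1L]) else NULL)
  prec <- crlb_precision_px(p, window, model) * pixel_size_nm
  stats::setNames(prec, c("precision_x", "precision_y"))
}

#' Radial-symmetry center of a spot window
#'
#' Non-iterative sub-pixel center estimate: the point minimizing the
#' weighted squared distance to the image-gradient lines, solved in closed
#' form. Exact for noiseless radially symmetric spots; requires no photon
#' calibration. Gradients are taken on the half-pixel dual grid from 2x2
#' cross differences, weighted by smoothed gradient magnitude squared over
#' the distance to the weighted gradient centroid.
#'
#' @param window image matrix, at least 3x3.
#' @return List with `x`, `y` (0-based px within the window) and `flagged`
#'   (`TRUE` when the gradient vanished everywhere and the geometric
#'   window center was returned).
#' @export
radial_symmetry_center <- function(window) {
  h <- nrow(window); w <- ncol(window)
  if (h < 3L || w < 3L) stop("window must be at least 3x3", call. = FALSE)
  # cross gradients on the dual grid (midpoints between pixel centers)
  du <- window[-1L, -1L, drop = FALSE] - window[-h, -w, drop = FALSE]  # (+x,+y)
  dv <- window[-h, -1L, drop = FALSE] - window[-1L, -w, drop = FALSE]  # (+x,-y)
  gx <- du + dv
  gy <- du - dv
  mag2 <- conv_sep(gx^2 + gy^2, rep(1, 3) / 3)   # 3x3 smoothing
  tot <- sum(mag2)
  xm <- outer(rep(1, h - 1L), seq_len(w - 1L) - 0.5)
  ym <- outer(seq_len(h - 1L) - 0.5, rep(1, w - 1L))
  if (tot <= .Machine$double.eps * max(1, sum(abs(window)))) {
    return(list(x = (w - 1) / 2, y = (h - 1) / 2, flagged = TRUE))
  }
  xc <- sum(mag2 * xm) / tot
  yc <- sum(mag2 * ym) / tot
  dcen <- sqrt((xm - xc)^2 + (ym - yc)^2)
  wgt <- mag2 / pmax(dcen, 0.5)
  g2 <- gx^2 + gy^2
  ok <- g2 > 0
  if (!any(ok)) return(list(x = (w - 1) / 2, y = (h - 1) / 2, flagged = TRUE))
  ux <- gx[ok] / sqrt(g2[ok]); uy <- gy[ok] / sqrt(g2[ok])
  wk <- wgt[ok]; rx <- xm[ok]; ry <- ym[ok]
  # minimize sum w * squared distance to the line through r along u:
  # A c = B with A = sum w (I - u u^T)
  a11 <- sum(wk * (1 - ux^2)); a12 <- sum(wk * (-ux * uy))
  a22 <- sum(wk * (1 - uy^2))
  b1 <- sum(wk * ((1 - ux^2) * rx - ux * uy * ry))
  b2 <- sum(wk * (-ux * uy * rx + (1 - uy^2) * ry))
  det <- a11 * a22 - a12^2
  if (!is.finite(det) || abs(det) < 1e-12 * max(a11, a22, 1)) {
    return(list(x = (w - 1) / 2, y = (h - 1) / 2, flagged = TRUE))
  }
  list(x = (a22 * b1 - a12 * b2) / det,
       y = (a11 * b2 - a12 * b1) / det,
       flagged = FALSE)
}
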