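test_that("the pixel-integrated model matches dense quadrature and conserves photons", {
  # constant image for N = 0
  m0 <- integrated_gaussian_model(0:6, 0:6, 3, 3, 0, 7, 1)
  expect_true(all(m0 == 7))
  # per-pixel agreement with an erf-free midpoint quadrature oracle
  m <- integrated_gaussian_model(0:6, 0:6, 3.3, 2.8, 50, 10, 1.1)
  for (px in c(1, 4, 6)) for (py in c(1, 3, 5)) {
    expect_equal(
      m[py + 1, px + 1],
      50 * quadrature_pixel_gaussian(px, py, 3.3, 2.8, 1.1) + 10,
      tolerance = 1e-4
    )
  }
  # photon conservation: N-term sums to N over a 15x15 window (~7.5 sigma)
  m15 <- integrated_gaussian_model(0:14, 0:14, 7, 7, 50, 0, 1.0)
  expect_equal(sum(m15), 50, tolerance = 1e-4)
  # mirror symmetry when centered
  mc <- integrated_gaussian_model(0:10, 0:10, 5, 5, 20, 1, 1.4)
  expect_equal(mc, mc[, 11:1]); expect_equal(mc, mc[11:1, ])
  expect_error(integrated_gaussian_model(0:4, 0:4, 2, 2, 1, 0, -1), "positive")
})

test_that("the optics formula gives sigma = 0.21 lambda / NA in pixel units", {
  expect_equal(psf_sigma_from_optics(670, 1.4, 100), 1.005)
  expect_equal(psf_sigma_from_optics(670, 1.4, 1), 100.5)
  expect_equal(psf_sigma_from_optics(670, 1.4, 200),
               psf_sigma_from_optics(670, 1.4, 100) / 2)
})

test_that("MLE recovers noiseless spot parameters to high accuracy", {
  frame <- render_spot_window(15, mu_x = 7.3, mu_y = 6.8, N = 50, b = 10,
                              sigma = 1)
  fit <- fit_mle(frame, c(7, 7), window = 11, sigma_init = 1.2,
                 pixel_size_nm = 100)
  expect_true(fit$converged)
  expect_equal(fit$x, 7.3, tolerance = 1e-3)
  expect_equal(fit$y, 6.8, tolerance = 1e-3)
  expect_equal(fit$N, 50, tolerance = 0.01 * 50)
  expect_equal(fit$b, 10, tolerance = 0.01 * 10)
  expect_equal(fit$sigma_x, 1, tolerance = 0.01)
  expect_gt(fit$precision_x, 0)
})

test_that("astigmatic MLE recovers widths and rotation of a rotated spot", {
  frame <- integrated_gaussian_model(0:16, 0:16, 8.2, 7.9, 400, 5,
                                     1.5, 1.0, 0.4)
  fit <- fit_mle(frame, c(8, 8), window = 15, model = "astigmatic",
                 sigma_init = 1.3)
  expect_true(fit$converged)
  expect_equal(fit$sigma_x, 1.5, tolerance = 0.02 * 1.5)
  expect_equal(fit$sigma_y, 1.0, tolerance = 0.02)
  expect_equal(fit$theta, 0.4, tolerance = 0.02)
  # isotropic and astigmatic fits agree on position for symmetric data
  sym <- render_spot_window(15, 7.25, 7.4, 200, 5, 1.2)
  fi <- fit_mle(sym, c(7, 7), window = 13, sigma_init = 1.2)
  fa <- fit_mle(sym, c(7, 7), window = 13, model = "astigmatic",
                sigma_init = 1.2)
  expect_equal(fi$x, fa$x, tolerance = 1e-2)
  expect_equal(fi$y, fa$y, tolerance = 1e-2)
})

test_that("fitting is equivariant under integer translation of the window content", {
  f1 <- integrated_gaussian_model(0:20, 0:20, 9.4, 10.6, 80, 8, 1.1)
  f2 <- integrated_gaussian_model(0:20, 0:20, 12.4, 7.6, 80, 8, 1.1)
  a <- fit_mle(f1, c(9, 11), window = 11)
  b <- fit_mle(f2, c(12, 8), window = 11)
  expect_equal(b$x - a$x, 3, tolerance = 1e-6)
  expect_equal(b$y - a$y, -3, tolerance = 1e-6)
})

test_that("all-zero windows flag non-convergence instead of erroring", {
  fit <- fit_mle(matrix(0, 21, 21), c(10, 10), window = 11)
  expect_false(fit$converged)
  expect_true(is.na(fit$x))
})

test_that("radial symmetry is exact for symmetric spots and flags flat windows", {
  win <- render_spot_window(15, 7, 7, 100, 5, 1.3)
  ctr <- radial_symmetry_center(win)
  expect_equal(ctr$x, 7, tolerance = 1e-6)
  expect_equal(ctr$y, 7, tolerance = 1e-6)
  expect_false(ctr$flagged)
  # sub-pixel shifted spot recovered within 0.02 px
  win2 <- render_spot_window(15, 7.25, 7.4, 100, 5, 1.3)
  ctr2 <- radial_symmetry_center(win2)
  expect_equal(ctr2$x, 7.25, tolerance = 0.02)
  expect_equal(ctr2$y, 7.4, tolerance = 0.02)
  # flat window falls back to the geometric center, flagged
  flat <- radial_symmetry_center(matrix(3, 11, 11))
  expect_true(flat$flagged)
  expect_equal(c(flat$x, flat$y), c(5, 5))
  expect_error(radial_symmetry_center(matrix(1, 2, 2)), "3x3")
})

test_that("CRLB precision decreases with N and approaches the shot-noise limit", {
  precs <- vapply(c(20, 50, 200, 1000), function(N) {
    loc <- tibble::tibble(x = 7, y = 7, N = N, b = 10, sigma_x = 1,
                          sigma_y = 1, theta = 0, converged = TRUE)
    localization_precision(loc, pixel_size_nm = 100, window = 15)[["precision_x"]]
  }, numeric(1))
  expect_true(all(diff(precs) < 0))
  # b -> 0 limit: sigma * a / sqrt(N) (here 100/sqrt(50) = 14.14 nm)
  loc0 <- tibble::tibble(x = 7, y = 7, N = 50, b = 1e-9, sigma_x = 1,
                         sigma_y = 1, theta = 0, converged = TRUE)
  p0 <- localization_precision(loc0, pixel_size_nm = 100, window = 15)
  expect_equal(unname(p0[["precision_x"]]), 100 / sqrt(50), tolerance = 0.1)
  expect_error(localization_precision(
    tibble::tibble(x = 1, y = 1, N = 5, b = 1, sigma_x = 1, converged = FALSE),
    100), "converged")
})

test_that("localization RMSE decreases monotonically with SNR on rendered spots", {
  set.seed(21)
  rmse_at <- function(N) {
    errs <- replicate(60, {
      truth <- c(7 + stats::runif(1, -0.5, 0.5), 7 + stats::runif(1, -0.5, 0.5))
      ref <- render_spot_window(15, truth[1], truth[2], N, 10, 1)
      noisy <- matrix(stats::rpois(length(ref), ref), nrow(ref))
      fit <- fit_mle(noisy, c(7, 7), window = 11, sigma_init = 1)
      if (fit$converged) sum((c(fit$x, fit$y) - truth)^2) else NA
    })
    sqrt(mean(errs, na.rm = TRUE))
  }
  r <- vapply(c(30, 120, 500), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))
})
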