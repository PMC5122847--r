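test_that("the dSTORM quality filter applies both cutoffs with the stated boundaries", {
  # sbr {0.5, 0.9} at sigma 1.42: only the second row passes sbr > 0.8
  locs <- tibble::tibble(frame = 0, x = 1:2, y = 1, N = 50, b = 10,
                         sigma_x = 1.42, sbr = c(0.5, 0.9))
  expect_equal(nrow(filter_localizations(locs, 0.8, 1.42, 0.4)), 1L)
  # sigma {0.9, 1.42, 1.9} at sbr 1: the window [1.02, 1.82] keeps only 1.42
  locs2 <- tibble::tibble(frame = 0, x = 1:3, y = 1, N = 50, b = 10,
                          sigma_x = c(0.9, 1.42, 1.9), sbr = 1)
  kept <- filter_localizations(locs2, 0.8, 1.42, 0.4)
  expect_equal(kept$sigma_x, 1.42)
  # the window is inclusive at its edges
  locs3 <- tibble::tibble(frame = 0, x = 1:2, y = 1, N = 1, b = 1,
                          sigma_x = c(1.02, 1.82), sbr = 1)
  expect_equal(nrow(filter_localizations(locs3, 0.8, 1.42, 0.4)), 2L)
  # permissive settings are the identity
  expect_equal(nrow(filter_localizations(locs2, 0, 1.42, Inf)), 3L)
})

test_that("cluster-track discarding removes only tracks strictly longer than the cutoff", {
  locs <- tibble::tibble(frame = c(0:29, 0:24, 5), x = 1, y = 1,
                         N = 1, b = 1, sigma_x = 1)
  tracks <- tibble::tibble(
    track_id = c(rep(1, 30), rep(2, 25)),
    frame = c(0:29, 0:24), x = 1, y = 1,
    loc_row = 1:55
  )
  out <- discard_cluster_tracks(locs, tracks, max_track_length = 25)
  expect_equal(nrow(out), 56 - 30)     # 30-point track removed entirely
  # a track of exactly 25 points is kept
  out25 <- discard_cluster_tracks(locs, tracks[tracks$track_id == 2, ],
                                  max_track_length = 25)
  expect_equal(nrow(out25), 56)
  # no tracks: identity
  expect_equal(nrow(discard_cluster_tracks(locs, tracks[0, ], 25)), 56)
})

test_that("super-resolution rendering conserves counts in both modes", {
  one <- tibble::tibble(x = 3.24, y = 5.87, precision_x = 10, precision_y = 10)
  img_c <- render_super_resolution(one, pixel_size_nm = 100, out_pixel_nm = 10,
                                   mode = "counts", field_nm = 1000)
  expect_equal(sum(img_c), 1)
  expect_equal(sum(img_c > 0), 1L)     # a single bin holds the count
  img_w <- render_super_resolution(one, pixel_size_nm = 100, out_pixel_nm = 10,
                                   mode = "precision_weighted", field_nm = 1000)
  expect_equal(sum(img_w), 1, tolerance = 1e-3)
  # additivity: two identical localizations double the image
  two <- dplyr::bind_rows(one, one)
  img_2 <- render_super_resolution(two, 100, 10, "precision_weighted",
                                   field_nm = 1000)
  expect_equal(img_2, 2 * img_w, tolerance = 1e-12)
  # missing precision columns fail fast in weighted mode
  expect_error(render_super_resolution(tibble::tibble(x = 1, y = 1), 100, 10),
               "precision")
})

test_that("displacements enumerate lags exactly and skip bridged gaps", {
  still <- tibble::tibble(track_id = 1, frame = 0:2, x = 4, y = 4)
  d0 <- compute_displacements(still, t_a = 0.01, max_lag = 2)
  expect_true(all(d0$displacement_px == 0))
  # positions 0,1,2,3 along x: lag-1 {1,1,1}, lag-2 {2,2}, lag-3 {3}
  walk <- tibble::tibble(track_id = 1, frame = 0:3, x = 0:3, y = 0)
  d <- compute_displacements(walk, t_a = 0.01, max_lag = 3)
  xs <- d[d$component == "x", ]
  expect_equal(sort(xs$displacement_px[xs$lag == 1]), c(1, 1, 1))
  expect_equal(sort(xs$displacement_px[xs$lag == 2]), c(2, 2))
  expect_equal(xs$displacement_px[xs$lag == 3], 3)
  # N-point track: lag-k sample size is N - k per component
  n <- 11
  tr <- tibble::tibble(track_id = 1, frame = 0:(n - 1), x = stats::runif(n),
                       y = stats::runif(n))
  dd <- compute_displacements(tr, t_a = 0.01, max_lag = 4)
  for (k in 1:4) {
    expect_equal(sum(dd$lag == k & dd$component == "x"), n - k)
  }
  # intervals across a bridged gap are excluded
  gappy <- tibble::tibble(track_id = 1, frame = c(0, 1, 3, 4),
                          x = c(0, 1, 3, 4), y = 0,
                          n_gaps = c(0, 0, 1, 0))
  dg <- compute_displacements(gappy, t_a = 0.01, max_lag = 2)
  dgx <- dg[dg$component == "x", ]
  expect_equal(sort(dgx$displacement_px[dgx$lag == 1]), c(1, 1))
  expect_equal(nrow(dgx[dgx$lag == 2, ]), 0L)
})

test_that("an exact linear MSD recovers D and epsilon to float precision", {
  D <- 10; t_a <- 1 / 950; eps_um2 <- 0.001; px <- 108
  mk <- function(k) {
    s2_um2 <- 2 * D * k * t_a + eps_um2
    s_px <- sqrt(s2_um2) * 1000 / px
    tibble::tibble(lag = k, lag_time_s = k * t_a,
                   component = rep(c("x", "y"), 30),
                   displacement_px = rep(c(s_px, -s_px), 30))
  }
  disp <- dplyr::bind_rows(lapply(1:5, mk))
  fit <- estimate_diffusion(disp, pixel_size_nm = px)
  expect_equal(fit$D_um2_s, 10, tolerance = 1e-10)
  expect_equal(fit$epsilon_um2, 0.001, tolerance = 1e-8)
  expect_false(fit$negative_D)
  # all-zero displacements give D = 0, epsilon = 0
  z <- dplyr::bind_rows(lapply(1:3, function(k) {
    tibble::tibble(lag = k, lag_time_s = k * t_a,
                   component = rep(c("x", "y"), 30),
                   displacement_px = 0)
  }))
  fz <- estimate_diffusion(z, pixel_size_nm = px)
  expect_equal(fz$D_um2_s, 0)
  expect_equal(fz$epsilon_um2, 0)
  # too few lags errors out
  expect_error(estimate_diffusion(mk(1), pixel_size_nm = px), "lag")
})

test_that("the histogram-fit variance agrees with the MLE asymptotically", {
  set.seed(51)
  t_a <- 1 / 950
  disp <- dplyr::bind_rows(lapply(1:3, function(k) {
    tibble::tibble(lag = k, lag_time_s = k * t_a,
                   component = rep(c("x", "y"), each = 4000),
                   displacement_px = stats::rnorm(8000, 0, sqrt(k)))
  }))
  f_mle <- estimate_diffusion(disp, pixel_size_nm = 100)
  f_hist <- estimate_diffusion(disp, pixel_size_nm = 100, method = "histogram")
  expect_equal(f_hist$D_um2_s, f_mle$D_um2_s, tolerance = 0.05)
})

test_that("diffusion estimates are invariant under translation and 90-degree rotation", {
  set.seed(52)
  sim <- simulate_brownian_movie(5, 1 / 950, n_particles = 40L,
                                 n_frames = 60L, render = FALSE, seed = 13)
  tr <- sim$truth_tracks
  base <- estimate_diffusion(compute_displacements(tr, 1 / 950, 4), 108)
  shifted <- dplyr::mutate(tr, x = x + 31, y = y - 17)
  rotated <- dplyr::mutate(tr, x0 = x, x = y, y = -x0)[c("track_id", "frame",
                                                         "x", "y")]
  f_s <- estimate_diffusion(compute_displacements(shifted, 1 / 950, 4), 108)
  f_r <- estimate_diffusion(compute_displacements(rotated, 1 / 950, 4), 108)
  expect_equal(f_s$D_um2_s, base$D_um2_s, tolerance = 1e-12)
  expect_equal(f_r$D_um2_s, base$D_um2_s, tolerance = 1e-12)
})

test_that("the estimate scales linearly with the true D", {
  Ds <- c(1, 5, 10)
  est <- vapply(Ds, function(D) {
    sim <- simulate_brownian_movie(D, 1 / 950, n_particles = 150L,
                                   n_frames = 120L, dims = c(1024L, 1024L),
                                   render = FALSE, seed = 14)
    d <- compute_displacements(sim$truth_tracks, 1 / 950, 5)
    estimate_diffusion(d, 108)$D_um2_s
  }, numeric(1))
  fitln <- stats::lm(est ~ Ds)
  expect_equal(unname(stats::coef(fitln)[2]), 1, tolerance = 0.1)
})

test_that("tidiers and plots expose the fitted quantities", {
  set.seed(53)
  sim <- simulate_brownian_movie(10, 1 / 950, n_particles = 30L,
                                 n_frames = 50L, render = FALSE, seed = 15)
  d <- compute_displacements(sim$truth_tracks, 1 / 950, 4)
  fit <- estimate_diffusion(d, 108)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit),
               c("D_um2_s", "epsilon_um2", "D_stderr", "n_lags", "negative_D"))
  expect_s3_class(autoplot(fit), "ggplot")
})
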