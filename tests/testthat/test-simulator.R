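test_that("star positions respect the arm geometry and rotational symmetry", {
  pos <- siemens_star_positions(n_arms = 10, grid = 256, rho = 7.5, seed = 4)
  expect_true(all(in_siemens_arm(pos$mu_x, pos$mu_y, 10, 256)))
  # 10-fold symmetry: counts per "on" sector are uniform (chi-squared)
  cx <- (256 - 1) / 2
  ang <- atan2(pos$mu_y - cx, pos$mu_x - cx) %% (2 * pi)
  sector <- floor(ang / (2 * pi / 10))
  p <- stats::chisq.test(table(sector))$p.value
  expect_gt(p, 0.01)
})

test_that("doubling the density doubles the expected emitter count", {
  n1 <- vapply(1:20, function(s) {
    nrow(siemens_star_positions(10, 128, rho = 4, seed = s))
  }, numeric(1))
  n2 <- vapply(1:20, function(s) {
    nrow(siemens_star_positions(10, 128, rho = 8, seed = 100 + s))
  }, numeric(1))
  # sums are Poisson; |sum2 - 2 sum1| within 3 sd of the difference
  m1 <- 20 * 4 * 128; m2 <- 20 * 8 * 128
  expect_lt(abs(sum(n2) - 2 * sum(n1)), 3 * sqrt(m2 + 4 * m1))
})

test_that("blinking kinetics reproduce the geometric and exponential identities", {
  kin <- blink_kinetics(k_on = 1 / 37.5, k_off = 1, k_bleach = 0.15)
  expect_equal(kin$p_bleach, 0.15 / 1.15)
  expect_equal(1 / kin$k_active, 1 / 1.15 + 37.5)
  n_em <- 10000L
  pos <- tibble::tibble(emitter_id = seq_len(n_em), mu_x = 0, mu_y = 0)
  truth <- simulate_blinking(pos, kin, n_frames = 5000L, seed = 9,
                             keep_events = TRUE)
  ev <- attr(truth, "events")
  # mean activations per emitter = 1/p_bleach = 1.15/0.15
  mean_act <- nrow(ev) / n_em
  sd_act <- sqrt((1 - kin$p_bleach) / kin$p_bleach^2 / n_em)
  expect_lt(abs(mean_act - 1 / kin$p_bleach), 3 * sd_act)
  # mean active duration = 1/k_deactivate = 1/1.15 frames
  mean_dur <- mean(ev$duration)
  sd_dur <- (1 / kin$k_deactivate) / sqrt(nrow(ev))
  expect_lt(abs(mean_dur - 1 / kin$k_deactivate), 3 * sd_dur)
  # A stays within (0, 1] and no emitter re-appears after bleaching
  expect_true(all(truth$A > 0 & truth$A <= 1))
})

test_that("k_on = 0 keeps all emitters dark forever", {
  kin <- blink_kinetics(k_on = 0)
  pos <- tibble::tibble(emitter_id = 1:5, mu_x = 1, mu_y = 1)
  truth <- simulate_blinking(pos, kin, 100, seed = 1)
  expect_equal(nrow(truth), 0L)
})

test_that("rendering conserves photons and reproduces the Poisson mean", {
  optics <- optics_config(N_photons = 50, background = 10)
  truth <- tibble::tibble(frame = 0, emitter_id = 1L, mu_x = 16, mu_y = 16,
                          A = 1)
  ren <- render_movie(truth, optics, dims = c(33L, 33L), seed = 2)
  expect_equal(sum(ren$reference[1, , ] - 10), 50, tolerance = 1e-4)
  # empty ground truth renders constant background
  ren0 <- render_movie(truth[0, ], optics, n_frames = 2, dims = c(8L, 8L),
                       seed = 1)
  expect_true(all(ren0$reference == 10))
  # mean over repeated noisy frames converges to the reference
  truth_rep <- tibble::tibble(frame = rep(0:99, each = 1), emitter_id = 1L,
                              mu_x = 10.3, mu_y = 11.7, A = 1)
  ren100 <- render_movie(truth_rep, optics, dims = c(24L, 24L), seed = 3)
  emp <- apply(ren100$movie$data, c(2, 3), mean)
  ref <- matrix(ren100$reference[1, , ], 24)
  dev <- (emp - ref) / sqrt(ref / 100)
  expect_lt(mean(abs(dev) > 3), 0.01)      # ~0.3% expected beyond 3 sigma
  expect_lt(abs(mean(dev)), 0.15)
})

test_that("SNR normalization hits the target on average", {
  optics <- optics_config()
  truth <- tibble::tibble(frame = rep(0:4, each = 3), emitter_id = 1:15,
                          mu_x = stats::runif(15, 8, 24),
                          mu_y = stats::runif(15, 8, 24),
                          A = stats::runif(15, 0.3, 1))
  ren <- render_movie(truth, optics, dims = c(32L, 32L), target_snr = 4,
                      seed = 5)
  peaks <- truth$A * ren$N_eff * spotlink:::peak_fraction(truth$mu_x, truth$mu_y,
                                                          optics$sigma_px)
  expect_equal(mean(peaks / sqrt(peaks + optics$background)), 4,
               tolerance = 1e-6)
  expect_error(render_movie(truth, optics, target_snr = -1), "positive")
})

test_that("the grid preset counts emitters exactly and never blinks", {
  gt <- make_grid_movie(render = FALSE)
  expect_equal(nrow(gt$truth), 896000L)
  expect_true(all(gt$truth$A == 1))
  small <- make_grid_movie(n_side = 2L, n_frames = 3L, render = FALSE)
  expect_equal(nrow(small$truth), 12L)
})

test_that("the siemens preset honors frame counts and is seed-deterministic", {
  a <- make_siemens_movie(grid = 64L, n_frames = 20L, n_emitters = 50L,
                          seed = 6)
  expect_equal(n_frames(a$movie), 20L)
  expect_equal(dim(a$movie$data)[2:3], c(64L, 64L))
  b <- make_siemens_movie(grid = 64L, n_frames = 20L, n_emitters = 50L,
                          seed = 6)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c2 <- make_siemens_movie(grid = 64L, n_frames = 20L, n_emitters = 50L,
                           seed = 7)
  expect_false(identical(a$movie$data, c2$movie$data))
})

test_that("Brownian steps have variance 2 D t_a and D = 0 freezes particles", {
  D <- 10; t_a <- 1 / 950; px <- 108
  sim <- simulate_brownian_movie(D, t_a, n_particles = 500L, n_frames = 201L,
                                 optics = optics_config(pixel_size_nm = px),
                                 dims = c(1024L, 1024L), seed = 8,
                                 render = FALSE)
  tr <- sim$truth_tracks
  steps_px <- unlist(lapply(split(tr, tr$track_id), function(p) {
    p <- p[order(p$frame), ]
    c(diff(p$x), diff(p$y))
  }))
  n <- length(steps_px)
  expect_equal(n, 500L * 200L * 2L)
  v_emp <- mean(steps_px^2) * (px / 1000)^2        # um^2
  v_true <- 2 * D * t_a
  expect_lt(abs(v_emp - v_true) / v_true, 3 * sqrt(2 / n) + 0.01)

  frozen <- simulate_brownian_movie(0, t_a, n_particles = 5L, n_frames = 10L,
                                    render = FALSE, seed = 1)
  ft <- frozen$truth_tracks
  expect_true(all(vapply(split(ft$x, ft$track_id),
                         function(v) diff(range(v)) == 0, logical(1))))

  again <- simulate_brownian_movie(D, t_a, n_particles = 5L, n_frames = 5L,
                                   dims = c(64L, 64L), seed = 12)
  again2 <- simulate_brownian_movie(D, t_a, n_particles = 5L, n_frames = 5L,
                                    dims = c(64L, 64L), seed = 12)
  expect_identical(again$movie$data, again2$movie$data)
})
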