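delta_frame <- function(n = 33, at = c(17, 17), height = 100, base = 0) {
  f <- matrix(base, n, n)
  f[at[1], at[2]] <- f[at[1], at[2]] + height
  f
}

test_that("bandpass filter removes DC and peaks on spikes", {
  expect_true(all(abs(bandpass_filter(matrix(7, 32, 32), 1, 4)) < 1e-12))
  f <- delta_frame()
  sc <- bandpass_filter(f, 1, 4)
  expect_equal(which.max(sc), which.max(f))
  # two equal spikes give two equal maxima
  f2 <- delta_frame(); f2[9, 9] <- 100
  sc2 <- bandpass_filter(f2, 1, 4)
  expect_equal(sc2[17, 17], sc2[9, 9], tolerance = 1e-10)
  expect_error(bandpass_filter(f, 4, 2), "feature_size")
})

test_that("cross-correlation scores the template location at ~1 and flat frames at 0", {
  sigma <- 1.2
  tmpl <- integrated_gaussian_model(0:8, 0:8, 4, 4, 50, 0, sigma)
  f <- matrix(3, 31, 31)
  f[11:19, 16:24] <- f[11:19, 16:24] + tmpl     # center at (x=19, y=14)
  sc <- crosscorr_score(f, sigma, window = 9)
  peak <- which(sc == max(sc), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(15, 20))    # row = y+1, col = x+1
  expect_gt(max(sc), 0.999)
  expect_true(all(sc >= -1 & sc <= 1))
  # additive constants do not change the score
  sc_shift <- crosscorr_score(f + 57, sigma, window = 9)
  expect_equal(sc, sc_shift, tolerance = 1e-8)
  # flat frame scores 0 by the zero-variance rule
  expect_true(all(crosscorr_score(matrix(5, 31, 31), sigma, 9) == 0))
  expect_error(crosscorr_score(matrix(0, 5, 5), 1, 7), "larger")
})

test_that("cross-correlation argmax equals brute-force correlation over shifts", {
  sigma <- 1.0
  f <- matrix(0, 41, 41)
  tm <- integrated_gaussian_model(0:10, 0:10, 5, 5, 80, 0, sigma)
  f[16:26, 6:16] <- tm       # spot center at (x=10, y=20), 0-based
  sc <- crosscorr_score(f, sigma, window = 11)
  peak <- which(sc == max(sc), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(21, 11))   # (row, col) = (y+1, x+1)

  # brute force: normalized correlation at every interior shift
  tmpl <- integrated_gaussian_model(0:10, 0:10, 5, 5, 1, 0, sigma)
  t0 <- tmpl - mean(tmpl)
  best <- c(-Inf, NA, NA)
  for (cy in 6:35) for (cx in 6:35) {
    patch <- f[(cy - 5):(cy + 5) + 1, (cx - 5):(cx + 5) + 1]
    p0 <- patch - mean(patch)
    den <- sqrt(sum(p0^2) * sum(t0^2))
    r <- if (den > 0) sum(p0 * t0) / den else 0
    if (r > best[1]) best <- c(r, cx, cy)
  }
  expect_equal(best[2:3], c(10, 20))
})

test_that("a-trous decomposition is exact and vanishes on constants", {
  cst <- atrous_decompose(matrix(4.2, 24, 24), 3)
  for (d in cst$details) expect_true(all(abs(d) < 1e-12))
  set.seed(3)
  f <- matrix(stats::rnorm(32 * 32), 32, 32)
  dec <- atrous_decompose(f, 4)
  expect_equal(Reduce(`+`, dec$details) + dec$smooth, f, tolerance = 1e-12)
})

test_that("wavelet plane 2 peaks at an isolated spot center", {
  f <- integrated_gaussian_model(0:32, 0:32, 20, 12, 500, 0, 1.3)
  sc <- wavelet_filter(f, 3, 2)
  peak <- which(unclass(sc) == max(sc), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(13, 21))   # (y+1, x+1)
  expect_true(is.finite(attr(sc, "threshold")))
})

test_that("filters are translation-equivariant on interior pixels", {
  set.seed(8)
  base <- matrix(stats::runif(28 * 28), 28, 28)
  f1 <- matrix(0, 40, 40); f1[7 + 1:28, 5 + 1:28] <- base
  f2 <- matrix(0, 40, 40); f2[9 + 1:28, 8 + 1:28] <- base   # shift (dy,dx)=(2,3)
  for (flt in list(
    function(m) bandpass_filter(m, 1, 3),
    function(m) crosscorr_score(m, 1, 7),
    function(m) wavelet_filter(m, 2, 2)
  )) {
    s1 <- unclass(flt(f1)); s2 <- unclass(flt(f2))
    # compare deep-interior region, away from padding influence
    expect_equal(s2[15:30, 15:30], s1[13:28, 12:27], tolerance = 1e-9)
  }
})

test_that("candidate extraction applies threshold, suppression, and tie rules", {
  sc <- matrix(0, 20, 20)
  expect_equal(nrow(find_candidates(sc, threshold = 0, min_distance = 3)), 0)

  # two maxima 3 px apart with min_distance 5: only the higher survives
  sc[10, 10] <- 5; sc[10, 13] <- 4
  got <- find_candidates(sc, threshold = 1, min_distance = 5)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$x, got$y), c(9, 9))
  # with min_distance 2 both survive, sorted by (y, x)
  got2 <- find_candidates(sc, threshold = 1, min_distance = 2)
  expect_equal(nrow(got2), 2L)
  expect_equal(got2$x, c(9, 12))

  # equal scores: the smaller (y, x) is kept
  sc2 <- matrix(0, 20, 20); sc2[8, 8] <- 3; sc2[8, 11] <- 3
  got3 <- find_candidates(sc2, threshold = 1, min_distance = 5)
  expect_equal(c(got3$x, got3$y), c(7, 7))

  # border exclusion drops edge maxima
  sc3 <- matrix(0, 20, 20); sc3[2, 2] <- 9; sc3[10, 10] <- 1
  got4 <- find_candidates(sc3, threshold = 0.5, min_distance = 3,
                          exclude_border = 5)
  expect_equal(c(got4$x, got4$y), c(9, 9))
})

test_that("candidate count decreases monotonically with threshold", {
  set.seed(12)
  f <- matrix(stats::rnorm(50 * 50), 50, 50)
  sc <- bandpass_filter(f, 1, 4)
  counts <- vapply(c(-1, 0, 0.1, 0.3, 1),
                   function(th) nrow(find_candidates(sc, th, 2)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the 16x16 grid frame yields exactly 256 candidates", {
  sim <- make_grid_movie(n_frames = 1L, seed = 2)
  bundle_frame <- get_frame(sim$movie, 0)
  sc <- wavelet_filter(bundle_frame, 3, 2)
  got <- find_candidates(sc, min_distance = 5, exclude_border = 5)
  expect_equal(nrow(got), 256L)
  # detected integer positions sit on the true grid within 1 px
  m <- match_localizations(sim$positions, got, radius = 1.5)
  expect_equal(m$n_tp, 256L)
})
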