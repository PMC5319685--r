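test_that("find_extrema locates strict interior extrema and handles plateaus", {
  e <- find_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_equal(e$maxima, c(2L, 6L))
  expect_equal(e$minima, 4L)

  ramp <- find_extrema(c(1, 2, 3, 4))
  expect_length(ramp$maxima, 0)
  expect_length(ramp$minima, 0)

  # plateau midpoint (rounded down) represents the whole flat top
  plateau <- find_extrema(c(0, 2, 2, 0))
  expect_equal(plateau$maxima, 2L)
  expect_length(plateau$minima, 0)
  wide <- find_extrema(c(0, 3, 3, 3, 3, 0))
  expect_equal(wide$maxima, 3L)

  expect_error(find_extrema(c(1, 2)), class = "emdcast_invalid_input")
})

test_that("envelopes of a dense sine hug +/- amplitude away from boundaries", {
  x <- sine_series(n = 256, period = 64)
  env <- compute_envelopes(x, "mirror")
  core <- 33:224
  expect_lt(max(abs(env$upper[core] - 1)), 0.05)
  expect_lt(max(abs(env$lower[core] + 1)), 0.05)
})

test_that("envelopes through constant-valued extrema are constant, two knots give a line", {
  # maxima all 4, minima all 2
  x <- rep(c(4, 3, 2, 3), 8)
  env <- compute_envelopes(x, "mirror")
  expect_equal(env$upper, rep(4, length(x)), tolerance = 1e-10)
  expect_equal(env$lower, rep(2, length(x)), tolerance = 1e-10)

  # natural spline with 2 knots degenerates to the straight line through them
  line <- stats::spline(c(2, 4), c(1, 0.5), xout = 1:5, method = "natural")$y
  expect_equal(line, seq(1.25, 0.25, by = -0.25))

  # clamp policy pins the envelope to the end samples and interpolates knots
  yy <- c(0, 1, 0, 0.5, 0, 0.8, 0, 0.3, 0)
  env2 <- compute_envelopes(yy, "clamp")
  expect_equal(env2$upper[c(2, 4, 6, 8)], c(1, 0.5, 0.8, 0.3))
  expect_equal(env2$upper[1], 0)
  expect_error(compute_envelopes(c(0, 1, 0, -1, 0)), class = "emdcast_not_siftable")
})

test_that("mean_envelope is the elementwise average and checks lengths", {
  expect_equal(mean_envelope(rep(4, 5), rep(2, 5)), rep(3, 5))
  u <- sine_series(32, 8)
  expect_equal(mean_envelope(u, -u), rep(0, 32))
  expect_equal(mean_envelope(c(1, 3), c(0, 1)), c(0.5, 2))
  expect_error(mean_envelope(1:3, 1:4), class = "emdcast_invalid_input")
})

test_that("is_imf accepts a pure sine and rejects ramps and offset sines", {
  expect_true(is_imf(sine_series(256, 32)))
  expect_false(is_imf(seq(0, 1, length.out = 50)))
  expect_false(is_imf(sine_series(256, 32) + 10))
})

test_that("sifting a pure sine is a fixed point reached within 2 iterations", {
  x <- sine_series(256, 32)
  s <- sift_one_imf(x)
  expect_lte(s$n_iterations, 2)
  expect_lt(max(abs(s$imf - x)), 1e-6)
})

test_that("sifting separates a sine from a slow trend", {
  st <- sine_plus_trend()
  s <- sift_one_imf(st$x)
  expect_gt(cor(s$imf, st$sine), 0.99)
  expect_lte(s$n_iterations, sift_config()$max_sift_iterations)
  expect_error(sift_one_imf(seq(1, 10, length.out = 20)),
               class = "emdcast_not_siftable")
})

test_that("decompose refuses short input and returns residue-only for monotone input", {
  expect_error(emd(monthly_series(1:7)), class = "emdcast_invalid_input")
  dec <- emd(monthly_series(cumsum(rep(c(1, 2), 10))))
  expect_equal(n_imfs(dec), 0L)
  expect_equal(dec$residue, as.numeric(cumsum(rep(c(1, 2), 10))))
})

test_that("known two-component signals decompose into the expected modes", {
  st <- sine_plus_trend()
  dec <- emd(monthly_series(st$x))
  expect_equal(n_imfs(dec), 1L)
  expect_gt(cor(dec$imf1, st$sine), 0.99)
  trend_range <- max(st$trend) - min(st$trend)
  expect_lt(sqrt(mean((dec$residue - st$trend)^2)), 0.05 * trend_range)

  ts2 <- two_sine()
  dec2 <- emd(monthly_series(ts2$x))
  expect_equal(n_imfs(dec2), 2L)
  expect_gt(cor(dec2$imf1, ts2$fast), 0.95)
  # extraction order goes from high to low frequency
  zc <- function(v) { s <- sign(v); s <- s[s != 0]; sum(diff(s) != 0) }
  expect_gt(zc(dec2$imf1), zc(dec2$imf2))
})

test_that("a pure sine yields exactly one intrinsic mode function", {
  dec <- emd(monthly_series(sine_series(128, 16)))
  expect_equal(n_imfs(dec), 1L)
})

test_that("reconstruction and determinism hold across seeded synthetic series", {
  for (s in c(1, 7, 42)) {
    x <- simulate_outpatient_series(seed = s)
    dec <- emd(x)
    recon <- rowSums(as.matrix(tibble::as_tibble(dec)[
      c(paste0("imf", seq_len(n_imfs(dec))), "residue")]))
    expect_lt(max(abs(x$value - recon)), 1e-8 * max(abs(x$value)))
  }
  x <- simulate_outpatient_series(seed = 3)
  expect_identical(emd(x), emd(x))
})

test_that("every extracted IMF satisfies the count condition", {
  zc <- function(v) { s <- sign(v); s <- s[s != 0]; sum(diff(s) != 0) }
  for (s in 1:10) {
    x <- simulate_outpatient_series(seed = s)
    dec <- emd(x)
    for (i in seq_len(n_imfs(dec))) {
      v <- dec[[paste0("imf", i)]]
      e <- find_extrema(v)
      expect_lte(abs(length(e$maxima) + length(e$minima) - zc(v)), 1)
    }
  }
})

test_that("tidy and glance views of a decomposition are consistent", {
  x <- simulate_outpatient_series(seed = 2)
  dec <- emd(x)
  long <- tidy(dec)
  expect_equal(nrow(long), nrow(dec) * (n_imfs(dec) + 1))
  expect_s3_class(long$component, "factor")
  g <- glance(dec)
  expect_equal(g$n_imfs, n_imfs(dec))
  expect_lt(g$reconstruction_error, 1e-10)
})
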