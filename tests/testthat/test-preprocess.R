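test_that("Savitzky-Golay smoothing reproduces polynomials and denoises", {
  n <- 201
  mz <- seq(2000, 2200, length.out = n)
  # constant and cubic trends pass through an order-3 filter unchanged
  s_const <- spec_(mz, rep(4, n))
  expect_equal(smooth_spectrum(s_const, 5)$intensity, rep(4, n))
  cubic <- 5 + 0.01 * (mz - 2100) + 2e-4 * (mz - 2100)^2 + 1e-6 * (mz - 2100)^3
  cubic <- cubic - min(cubic) + 1
  s_cubic <- spec_(mz, cubic)
  expect_equal(smooth_spectrum(s_cubic, 5)$intensity, cubic, tolerance = 1e-9)

  set.seed(7)
  peak <- 50 * exp(-(mz - 2100)^2 / 50) + 10
  noisy <- peak + rnorm(n, 0, 2)
  sm <- smooth_spectrum(spec_(mz, pmax(noisy, 0)), 8)
  expect_lt(sd(sm$intensity - peak), sd(noisy - peak))

  expect_error(smooth_spectrum(spec_(mz[1:5], rep(1, 5)), 3), "longer than")
  expect_error(smooth_spectrum(s_const, 1), ">= 2")
})

test_that("top-hat baseline subtraction matches the morphology oracle", {
  mz <- seq(3000, 3049)
  # flat spectrum -> all zero
  expect_equal(subtract_baseline(spec_(mz, rep(3, 50)), 4)$intensity,
               rep(0, 50))
  # isolated spike survives exactly
  y <- rep(0, 50); y[25] <- 9
  expect_equal(subtract_baseline(spec_(mz, y), 1)$intensity, y)

  # ramp + narrow peaks vs brute-force erosion/dilation oracle
  set.seed(11)
  ramp <- seq(0, 10, length.out = 50)
  y2 <- ramp; y2[c(10, 30, 44)] <- y2[c(10, 30, 44)] + c(20, 35, 15)
  for (h in c(2, 5, 9)) {
    got <- subtract_baseline(spec_(mz, y2), h)$intensity
    expect_equal(got, y2 - oracle_opening(y2, h))
  }
  # peak height kept to within the ramp's rise over one window (~1.4) + 1%
  got <- subtract_baseline(spec_(mz, y2), 3)$intensity
  expect_lt(abs(got[30] - 35), 0.01 * 35 + 1.5)

  # idempotence: opening is a morphological filter
  s1 <- subtract_baseline(spec_(mz, y2), 5)
  expect_equal(subtract_baseline(s1, 5)$intensity, s1$intensity)
})

test_that("TIC normalization and degenerate input", {
  s <- spec_(c(2000, 3000), c(2, 2))
  expect_equal(normalize_tic(s)$intensity, c(0.5, 0.5))
  expect_equal(normalize_tic(spec_(c(2000, 3000), c(1, 3)))$intensity,
               c(0.25, 0.75))
  set.seed(2)
  r <- spec_(seq(2000, 2100), runif(101))
  expect_equal(sum(normalize_tic(r)$intensity), 1, tolerance = 1e-9)
  expect_error(normalize_tic(spec_(c(2000, 3000), c(0, 0))), "all-zero")
})

test_that("noise estimation is a scaled MAD", {
  set.seed(42)
  mz <- seq_len(10000) + 2000
  s <- spec_(mz, abs(rnorm(10000)) + 5)  # shift keeps intensities positive
  # MAD of N(5,1)-like data consistent for sd 1
  s2 <- spec_(mz, rnorm(10000, 50, 1))
  expect_gt(estimate_noise(s2), 0.95)
  expect_lt(estimate_noise(s2), 1.05)
  expect_equal(estimate_noise(spec_(mz[1:20], rep(7, 20))), 0)
  expect_equal(estimate_noise(spec_(mz[1:10], c(rep(0, 9), 100))), 0)
  expect_error(estimate_noise(spec_(mz[1:5], 1:5)), ">= 10")
})

test_that("peak detection matches the exhaustive scan oracle", {
  mz <- seq(5000, 5199)
  y <- 100 * exp(-(mz - 5100)^2 / 18)
  set.seed(9)
  y <- y + abs(rnorm(200, 0, 0.5))
  s <- spec_(mz, y)
  pl <- detect_peaks(s, 10, 5)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$mz, 5100)

  # two apices 3 points apart, half_window 5: taller only
  y2 <- rep(0.001, 200); y2[80] <- 10; y2[83] <- 8
  set.seed(1); y2 <- y2 + abs(rnorm(200, 0, 0.01))
  pl2 <- detect_peaks(spec_(mz, y2), 5, 3)
  expect_true(mz[80] %in% pl2$mz)
  expect_false(mz[83] %in% pl2$mz)

  # 30-peak synthetic spectrum == brute-force scan
  set.seed(5)
  y3 <- rep(0, 1000)
  apex <- sample(20:980, 30)
  for (a in apex) y3 <- y3 + runif(1, 5, 60) *
      exp(-(seq_len(1000) - a)^2 / runif(1, 2, 30))
  y3 <- y3 + abs(rnorm(1000, 0, 1))
  s3 <- spec_(seq_len(1000) + 2000, y3)
  noise <- estimate_noise(s3)
  pl3 <- detect_peaks(s3, 12, 3)
  expect_equal(pl3$mz - 2000, oracle_peaks(y3, 12, 3, noise))
  expect_equal(pl3$snr, y3[pl3$mz - 2000] / noise)
})

test_that("peak detection equals the oracle over random parameter draws", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(200:1000, 1)
    y <- abs(rnorm(n, 0, 1))
    for (a in sample(seq_len(n), 10)) y[a] <- y[a] + runif(1, 0, 30)
    hw <- sample(2:40, 1); snr <- runif(1, 1, 8)
    s <- spec_(seq_len(n) + 3000, y)
    pl <- detect_peaks(s, hw, snr)
    expect_equal(pl$mz - 3000, oracle_peaks(y, hw, snr, estimate_noise(s)),
                 info = sprintf("rep %d hw %d", rep, hw))
  }
})

test_that("zero-noise spectra flag infinite SNR", {
  mz <- seq(2000, 2099)
  y <- rep(0, 100); y[50] <- 10
  pl <- detect_peaks(spec_(mz, y), 5, 3)
  expect_true(attr(pl, "zero_noise"))
  expect_equal(pl$snr, Inf)
})

test_that("replicate averaging with shared and offset grids", {
  mz <- seq(2000, 2004)
  a <- spec_(c(2000, 3000), c(1, 3)); b <- spec_(c(2000, 3000), c(3, 1))
  expect_equal(average_replicates(list(a))$intensity, a$intensity)
  expect_equal(average_replicates(list(a, b))$intensity, c(2, 2))

  # grid offset by 0.5 Da: manual linear interpolation on 5 points
  g1 <- spec_(mz, c(2, 4, 6, 4, 2))
  g2 <- spec_(mz + 0.5, c(10, 20, 30, 20, 10))
  avg <- average_replicates(list(g1, g2))
  interp <- c(10, 15, 25, 25, 15)  # rule-2 clamp at left edge, midpoints after
  expect_equal(avg$intensity, (c(2, 4, 6, 4, 2) + interp) / 2)
  expect_error(average_replicates(list()), "no spectra")
})

test_that("preprocess outputs always satisfy spectrum invariants", {
  lib <- generate_library(synth_config(n_species = 2, strains_per_species = 2,
                                       mass_range = c(1880, 5000), seed = 8))
  for (s in lib$spectra) {
    out <- preprocess_profile(s, param_set(baseline_halfwindow = 50))
    expect_true(all(diff(out$mz) > 0))
    expect_true(all(out$intensity >= 0))
    expect_equal(sum(out$intensity), 1, tolerance = 1e-9)
  }
})
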