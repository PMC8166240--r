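test_that("parameter sampling is seeded, bounded and uniform", {
  r <- param_ranges()
  p1 <- sample_params(r, rng_seed = 99)
  p2 <- sample_params(r, rng_seed = 99)
  expect_identical(unclass(p1), unclass(p2))
  for (nm in names(unclass(p1))) {
    expect_gte(p1[[nm]], r[[nm]][1])
    expect_lte(p1[[nm]], r[[nm]][2])
  }
  # degenerate range pins the value
  rd <- param_ranges(peak_halfwindow = c(7, 7))
  draws <- replicate(20, sample_params(rd)$peak_halfwindow)
  expect_true(all(draws == 7L))

  # integer field on [1, 10]: all values seen, frequencies in binomial 99% band
  ru <- param_ranges(align_halfwindow = c(1, 10))
  set.seed(4)
  v <- replicate(1000, sample_params(ru)$align_halfwindow)
  tab <- table(factor(v, levels = 1:10))
  expect_true(all(tab > 0))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_true(all(tab >= bounds[1] & tab <= bounds[2]))

  expect_error(param_ranges(align_snr = c(5, 1)), "invalid bounds")
})

test_that("BTS objective scores reproducibility across targets", {
  cfg <- synth_config(seed = 33, target_drift = 0, noise_sd = 0,
                      baseline_amplitude = 0, mass_range = c(1880, 9000))
  bts <- generate_bts(cfg, n_targets = 2, replicates_per_target = 2)
  ob <- objective_bts(bts, param_set())
  expect_false(ob$failed)
  expect_equal(ob$mean_jaccard, 1)       # identical spectra on both targets

  # disjoint peak sets across targets -> Jaccard 0
  cfg2 <- synth_config(seed = 34, noise_sd = 0, baseline_amplitude = 0,
                       mass_range = c(1880, 9000), bts_n_peaks = 5)
  b1 <- generate_bts(cfg2, n_targets = 1, replicates_per_target = 1)
  cfg3 <- synth_config(seed = 99, noise_sd = 0, baseline_amplitude = 0,
                       mass_range = c(1880, 9000), bts_n_peaks = 5)
  b2 <- generate_bts(cfg3, n_targets = 1, replicates_per_target = 1)
  b2[[1]]$target_id <- "T2"
  ob2 <- objective_bts(c(b1, b2), param_set(align_tolerance = 5e-4))
  expect_equal(ob2$mean_jaccard, 0)

  # extreme parameters fail softly, scoring 0
  ob3 <- objective_bts(bts, param_set(smooth_halfwindow = 10000))
  expect_true(ob3$failed)
  expect_equal(ob3$mean_jaccard, 0)
  expect_error(objective_bts(b1, param_set()), ">= 2 targets")
})

test_that("loop 1 is reproducible and its running maximum non-decreasing", {
  cfg <- synth_config(seed = 12, mass_range = c(1880, 8000))
  bts <- generate_bts(cfg)
  r <- param_ranges()
  l1a <- run_loop1(bts, r, n_iter = 6, seed = 7)
  l1b <- run_loop1(bts, r, n_iter = 6, seed = 7)
  expect_identical(l1a$trace, l1b$trace)
  expect_true(all(diff(cummax(l1a$trace$mean_jaccard)) >= 0))
  l1c <- run_loop1(bts, r, n_iter = 1, seed = 3)
  expect_equal(nrow(l1c$trace), 1)
  expect_identical(unclass(l1c$best),
                   unclass(maldidrep:::trace_row_params(l1c$trace[1, ])))
})

test_that("loop 1 recovers a workable alignment tolerance", {
  # drift of 1e-3 between targets: tolerances well below it split the
  # conserved BTS peaks, tolerances above match them
  cfg <- synth_config(seed = 55, target_drift = 1e-3,
                      mass_range = c(1880, 8000))
  bts <- generate_bts(cfg)
  r <- param_ranges()
  hits <- 0
  for (s in 1:10) {
    best <- run_loop1(bts, r, n_iter = 12, seed = s)$best
    if (best$align_tolerance > 5e-4) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("QC filter applies the SNR/peak-count rule", {
  mk <- function(n, snr, id) pl_(seq(3000, by = 50, length.out = n),
                                 intensity = rev(seq_len(n)),
                                 snr = snr, id = id)
  # 12 peaks, all SNR 100 -> fails on count
  r1 <- qc_filter(list(mk(12, rep(100, 12), "a")))
  expect_false(r1$passed)
  expect_equal(r1$n_peaks, 12)
  # 20 peaks, top-10 median 14.9 -> fails on SNR
  snrs <- c(rep(14.9, 10), rep(200, 10))  # top-10 by intensity get 14.9
  r2 <- qc_filter(list(mk(20, snrs, "b")))
  expect_false(r2$passed)
  expect_equal(r2$median_snr_top10, 14.9)
  # 13 peaks at SNR 15 passes both gates exactly
  r3 <- qc_filter(list(mk(13, rep(15, 13), "c")))
  expect_true(r3$passed)
  # fewer than top_k peaks: median over all; empty list fails
  r4 <- qc_filter(list(mk(14, rep(16, 14), "d"),
                       pl_(numeric(0), numeric(0), numeric(0), id = "e")))
  expect_true(r4$passed[1])
  expect_false(r4$passed[2])
})

test_that("discrimination overlap is the balanced misclassification minimum", {
  # perfectly separable classes
  expect_equal(overlap_metric(within = c(0.9, 0.85), between = c(0.1, 0.2)), 0)
  # identical distributions are indistinguishable
  expect_equal(overlap_metric(within = c(0.5, 0.7), between = c(0.5, 0.7)), 0.5)
  # hand-worked case: best threshold in (0.7, 0.8] misclassifies half the
  # within-pairs and none of the between-pairs -> (1/2 + 0)/2 = 0.25
  expect_equal(overlap_metric(within = c(0.8, 0.6), between = 0.7), 0.25)
  # exhaustive check against brute force over a fine threshold grid
  set.seed(19)
  for (rep in 1:5) {
    w <- runif(7); b <- runif(5)
    grid <- sort(unique(c(w, b, w + 1e-9, b + 1e-9, 0, 1)))
    brute <- min(sapply(grid, function(t)
      (mean(w < t) + mean(b >= t)) / 2))
    expect_equal(overlap_metric(w, b), brute)
    # invariance under a strictly monotone transform
    expect_equal(overlap_metric(w^3, b^3), brute)
  }
  # the matrix wrapper reads upper-tri pairs by label
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.9; M[1, 3] <- M[3, 1] <- 0.2
  M[2, 3] <- M[3, 2] <- 0.1
  lab <- matrix(FALSE, 3, 3); lab[1, 2] <- lab[2, 1] <- TRUE
  expect_equal(objective_discrimination(M, lab), 0)
})

test_that("overlap errors name the missing class", {
  M <- diag(3); M[1, 2] <- M[2, 1] <- 0.5
  lab <- matrix(TRUE, 3, 3)
  expect_error(objective_discrimination(M, lab), "between")
  expect_error(objective_discrimination(M, !lab), "within")
})

test_that("pair labels come from the identity cutoff", {
  ids <- c("a", "b", "c")
  m <- matrix(c(100, 99.5, 85, 99.5, 100, 85, 85, 85, 100), 3, 3,
              dimnames = list(ids, ids))
  lab <- pair_labels(identity_matrix(m), ids)
  expect_true(lab["a", "b"])
  expect_false(lab["a", "c"])
  expect_error(pair_labels(identity_matrix(m), c("a", "zzz")), "missing")
})

test_that("loop 2 is seeded and its running minimum non-increasing", {
  lib <- generate_library(synth_config(n_species = 4, strains_per_species = 3,
                                       mass_range = c(1880, 8000), seed = 61))
  l2a <- run_loop2(lib$spectra, lib$identity, n_iter = 5, seed = 11)
  l2b <- run_loop2(lib$spectra, lib$identity, n_iter = 5, seed = 11)
  expect_identical(l2a$trace, l2b$trace)
  expect_true(all(diff(cummin(l2a$trace$overlap)) <= 0))
  l21 <- run_loop2(lib$spectra, lib$identity, n_iter = 1, seed = 2)
  expect_equal(nrow(l21$trace), 1)
})
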