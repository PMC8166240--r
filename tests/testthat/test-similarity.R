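test_that("Jaccard matrix: shared/union arithmetic and edge cases", {
  # 20 shared bins, union 21 -> 0.952 (three decimals)
  P <- rbind(rep(1, 21),
             c(rep(1, 20), 0))
  fm <- fm_(P)
  J <- jaccard_matrix(fm)
  expect_equal(round(J[1, 2], 3), 0.952)
  expect_equal(J[1, 2], 20 / 21)

  expect_equal(jaccard_matrix(fm_(rbind(c(1, 1, 0), c(1, 1, 0))))[1, 2], 1)
  expect_equal(jaccard_matrix(fm_(rbind(c(1, 1, 0), c(0, 0, 1))))[1, 2], 0)
  # two empty presence rows: union empty -> 0 by convention, flagged
  J0 <- jaccard_matrix(fm_(rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0))))
  expect_equal(J0[2, 3], 0)
  expect_equal(nrow(attr(J0, "empty_union")), 1)
})

test_that("cosine matrix: scale invariance, orthogonality, hand value", {
  C <- cosine_matrix(fm_(rbind(c(1, 2, 0), c(2, 4, 0))))
  expect_equal(C[1, 2], 1)
  expect_equal(cosine_matrix(fm_(rbind(c(1, 0), c(0, 1))))[1, 2], 0)
  expect_equal(cosine_matrix(fm_(rbind(c(1, 1, 0), c(1, 0, 1))))[1, 2], 0.5)
  Z <- cosine_matrix(fm_(rbind(c(1, 1, 0), c(0, 0, 0))))
  expect_equal(Z[1, 2], 0)
  expect_equal(attr(Z, "zero_rows"), 2L)
})

test_that("similarity matrices agree with brute-force oracles", {
  set.seed(23)
  for (rep in 1:5) {
    X <- matrix(rlnorm(10 * 20), 10, 20) * matrix(rbinom(200, 1, 0.4), 10, 20)
    fm <- fm_(X)
    J <- jaccard_matrix(fm); C <- cosine_matrix(fm)
    for (i in 1:9) for (j in (i + 1):10) {
      a <- which(X[i, ] > 0); b <- which(X[j, ] > 0)
      jo <- if (length(union(a, b)) == 0) 0 else
        length(intersect(a, b)) / length(union(a, b))
      expect_equal(J[i, j], jo)
      co <- sum(X[i, ] * X[j, ]) /
        (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
      expect_equal(C[i, j], co)
    }
    # symmetry / diagonal / range invariants
    for (M in list(J, C)) {
      expect_equal(unname(M), unname(t(M)))
      expect_equal(unname(diag(M)), rep(1, 10))
      expect_true(all(M >= 0 & M <= 1))
    }
  }
})

test_that("adding a shared bin never decreases Jaccard", {
  set.seed(31)
  for (rep in 1:10) {
    P <- matrix(rbinom(2 * 15, 1, 0.5), 2, 15)
    P2 <- cbind(P, c(1, 1))
    j1 <- jaccard_matrix(fm_(P, bin_mz = 1:15 * 1000))[1, 2]
    j2 <- jaccard_matrix(fm_(P2, bin_mz = 1:16 * 1000))[1, 2]
    expect_gte(j2, j1)
  }
})

test_that("hyperbolic model: y0 estimation and identities", {
  # construct J/C where all low-J pairs have cosine 0.27
  n <- 8
  J <- matrix(0.01, n, n); diag(J) <- 1
  C <- matrix(0.27, n, n); diag(C) <- 1
  m <- fit_hyperbolic(J, C, epsilon = 0.05)
  expect_equal(m$y0, 0.27)
  expect_equal(predict(m, 0), m$y0)               # y_hat(0) = y0
  expect_equal(predict(m, 0.2), m$y0 + 0.5)       # 0.2/(0.2+0.2)
  # fallback to lowest decile with warning when too few low-J pairs
  Jh <- matrix(0.5, n, n); diag(Jh) <- 1
  expect_warning(fit_hyperbolic(Jh, C, epsilon = 0.05), "lowest decile")
})

test_that("weighted cosine follows the combiner algebra", {
  m <- structure(list(y0 = 0.25, saturation = 0.2, n_pairs = 10),
                 class = "hyperbolic_model")
  C <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  J0 <- matrix(c(1, 0, 0, 1), 2, 2)
  W <- weight_cosine(C, J0, m)
  expect_equal(W[1, 2], 0.8 * 0.25)        # multiply combiner at J = 0
  expect_equal(diag(W), c(1, 1))

  # clamp: J = 1 with y0 = 0.2 predicts 1.033 -> factor 1
  m2 <- structure(list(y0 = 0.2, saturation = 0.2, n_pairs = 10),
                  class = "hyperbolic_model")
  J1 <- matrix(1, 2, 2)
  C1 <- matrix(1, 2, 2)
  expect_equal(weight_cosine(C1, J1, m2)[1, 2], 1)

  # W <= C elementwise whenever the factor is clamped to <= 1
  set.seed(5)
  Cr <- matrix(runif(16), 4, 4); Cr <- (Cr + t(Cr)) / 2; diag(Cr) <- 1
  Jr <- matrix(runif(16, 0, 0.4), 4, 4); Jr <- (Jr + t(Jr)) / 2; diag(Jr) <- 1
  Wr <- weight_cosine(Cr, Jr, m)
  off <- upper.tri(Wr)
  expect_true(all(Wr[off] <= Cr[off]))
  # alternative combiners
  expect_equal(weight_cosine(C, J0, m, "min")[1, 2], 0.25)
  expect_equal(weight_cosine(C, J0, m, "geometric_mean")[1, 2],
               sqrt(0.8 * 0.25))
})

test_that("similarity bundle invariants hold on a synthetic library", {
  lib <- generate_library(synth_config(n_species = 3, strains_per_species = 3,
                                       mass_range = c(1880, 8000), seed = 17))
  fm <- align_library(lib$spectra, param_set())
  sim <- similarity_bundle(fm)
  for (M in list(sim$jaccard, sim$cosine, sim$weighted)) {
    expect_equal(unname(M), unname(t(M)))
    expect_equal(unname(diag(M)), rep(1, nrow(M)))
    expect_true(all(M >= 0 & M <= 1))
  }
})
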