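# 4PL used by the generator-side oracle
fpl <- function(x, lower, upper, mid, scal)
  lower + (upper - lower) / (1 + exp((mid - x) / scal))

test_that("sigmoid fit recovers a known midpoint and is exact when noiseless", {
  set.seed(66)
  x <- runif(300, 0, 1)
  y <- fpl(x, 85, 99.8, 0.66, 0.06) + rnorm(300, 0, 1)
  m <- fit_sigmoid(x, y)
  expect_lt(abs(m$midpoint - 0.66), 0.03)
  expect_gt(m$r_squared, 0.8)

  y0 <- fpl(x, 85, 99.8, 0.66, 0.06)
  m0 <- fit_sigmoid(x, y0)
  expect_gt(m0$r_squared, 0.999)
  expect_lt(abs(m0$midpoint - 0.66), 1e-4)

  # reflecting x about the midpoint flips the slope, not the midpoint
  mr <- fit_sigmoid(2 * 0.66 - x, y0)
  expect_lt(abs(mr$midpoint - 0.66), 1e-3)
  dir0 <- predict(m0$fit, newdata = data.frame(x = 0.8)) -
          predict(m0$fit, newdata = data.frame(x = 0.5))
  dirr <- predict(mr$fit, newdata = data.frame(x = 0.8)) -
          predict(mr$fit, newdata = data.frame(x = 0.5))
  expect_lt(dir0 * dirr, 0)

  expect_error(fit_sigmoid(x[1:5], y[1:5]), ">= 10")
  expect_error(fit_sigmoid(x, rep(90, 300)), "degenerate")
  # threshold rule: midpoint 0.66 -> operating threshold 0.65
  expect_equal(threshold_from_sigmoid(m0), 0.65)
})

test_that("MTU clustering cuts the average-linkage tree at the threshold", {
  ids <- paste0("s", 1:5)
  W <- matrix(0.1, 5, 5, dimnames = list(ids, ids))
  W[1:2, 1:2] <- 0.9; W[3:5, 3:5] <- 0.9; diag(W) <- 1
  res <- cluster_mtus(W, threshold = 0.65)
  expect_equal(res$n_mtus, 2)
  expect_equal(res$table$mtu_id, c(1, 1, 2, 2, 2))
  expect_equal(res$replicated, 2)
  expect_equal(res$singletons, 0)
  # brute-force average-linkage oracle at the same cut
  oracle <- oracle_linkage_cut(1 - W, "average", 1 - 0.65)
  expect_equal(adjusted_rand_index(res$table$mtu_id, oracle), 1)

  # threshold near 1: everything is a singleton; near 0: one MTU
  set.seed(8)
  R <- matrix(runif(25, 0, 0.6), 5, 5); R <- (R + t(R)) / 2; diag(R) <- 1
  dimnames(R) <- list(ids, ids)
  expect_equal(cluster_mtus(R, 0.99)$n_mtus, 5)
  expect_equal(cluster_mtus(R, 0.01)$n_mtus, 1)
  expect_error(cluster_mtus(R, 0), "threshold")
  Rbad <- R; Rbad[1, 2] <- 0.9
  expect_error(cluster_mtus(Rbad, 0.5), "symmetric")
})

test_that("clustering matches the brute-force linkage oracle on random cases", {
  set.seed(41)
  for (method in c("average", "complete", "single")) for (rep in 1:4) {
    n <- 6
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 1
    dimnames(W) <- list(paste0("x", 1:n), paste0("x", 1:n))
    thr <- runif(1, 0.2, 0.8)
    got <- cluster_mtus(W, thr, linkage = method)$table$mtu_id
    oracle <- oracle_linkage_cut(1 - W, method, 1 - thr)
    expect_equal(adjusted_rand_index(got, oracle), 1,
                 info = paste(method, rep))
  }
})

test_that("MTU count is monotone in threshold and merges never invert", {
  set.seed(14)
  n <- 12
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 1
  dimnames(W) <- list(paste0("s", 1:n), paste0("s", 1:n))
  thr <- seq(0.05, 0.95, by = 0.05)
  counts <- sapply(thr, function(t) cluster_mtus(W, t)$n_mtus)
  expect_true(all(diff(counts) >= 0))  # lower threshold -> fewer MTUs
  hc <- cluster_mtus(W, 0.5)$hclust
  expect_true(all(diff(hc$height) >= -1e-12))
  # thresholds inside one flat region of the dendrogram give one partition
  h <- sort(hc$height)
  gaps <- which(diff(h) > 0.02)
  if (length(gaps)) {
    lo <- 1 - (h[gaps[1] + 1] - 0.005); hi <- 1 - (h[gaps[1]] + 0.005)
    expect_equal(cluster_mtus(W, lo)$table$mtu_id,
                 cluster_mtus(W, hi)$table$mtu_id)
  }
})

test_that("bootstrap support: identical pairs, strong clades, determinism", {
  set.seed(3)
  # two well-separated species, 4 strains each, 40 bins
  base <- rbind(matrix(rlnorm(4 * 20, 3, 0.2), 4, 20), matrix(0, 4, 20))
  base2 <- rbind(matrix(0, 4, 20), matrix(rlnorm(4 * 20, 3, 0.2), 4, 20))
  X <- cbind(base, base2) + matrix(rlnorm(8 * 40, -2, 0.3), 8, 40)
  fm <- fm_(X, ids = paste0("s", 1:8))
  sup <- bootstrap_support(fm, n_boot = 200, seed = 5)
  hc <- attr(sup, "hclust")
  # find the two 4-leaf species clades
  keys <- maldidrep:::clade_keys(hc)
  four <- which(sup$n_leaves == 4)
  expect_gte(length(four), 2)
  expect_true(all(sup$bp[four] >= 0.95))
  # duplicated spectrum pair: bp = 1 for its 2-leaf clade
  Xd <- rbind(X, X[1, , drop = FALSE] * 1.0000001)
  fmd <- fm_(Xd, ids = c(paste0("s", 1:8), "dup"))
  supd <- bootstrap_support(fmd, n_boot = 150, seed = 5)
  hcd <- attr(supd, "hclust")
  kd <- maldidrep:::clade_keys(hcd)
  pair_node <- which(kd$keys == paste(sort(c("s1", "dup")), collapse = "\r"))
  expect_equal(supd$bp[pair_node], 1)
  # determinism under seed
  sup2 <- bootstrap_support(fm, n_boot = 200, seed = 5)
  expect_identical(sup$bp, sup2$bp)
  expect_error(bootstrap_support(fm, n_boot = 50), ">= 100")
})

test_that("AU values accompany BP under the multiscale flag", {
  set.seed(3)
  X <- cbind(matrix(rlnorm(6 * 15, 3, 0.3), 6, 15),
             matrix(rlnorm(6 * 15, 0, 0.3), 6, 15))
  X[4:6, 1:15] <- X[4:6, 1:15] * 0.01
  fm <- fm_(X, ids = paste0("s", 1:6))
  sup <- bootstrap_support(fm, n_boot = 120, seed = 2, au = TRUE)
  expect_true("au" %in% names(sup))
  expect_true(all(sup$au >= 0 & sup$au <= 1, na.rm = TRUE))
})

test_that("newick export carries support labels and parses", {
  set.seed(4)
  X <- matrix(rlnorm(5 * 12), 5, 12)
  fm <- fm_(X, ids = letters[1:5])
  sup <- bootstrap_support(fm, n_boot = 100, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  nwk <- write_newick(sup, f)
  txt <- readLines(f)
  expect_match(txt, "^\\(.*\\)[0-9]+;$")
  leaves <- setdiff(strsplit(gsub("[():;0-9.|]+", ",", txt), ",")[[1]], "")
  expect_setequal(leaves, letters[1:5])
})

test_that("adjusted Rand index behaves", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  set.seed(1)
  a <- rep(1:2, 50)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.2)
  expect_equal(adjusted_rand_index(1:4, 1:4), 1)
})
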