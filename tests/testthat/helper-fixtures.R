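# shared fixtures and independent oracles

# spectrum helper with a wide declared range so tiny grids are legal
spec_ <- function(mz, intensity, id = "s", ...) {
  maldi_spectrum(mz, intensity, spectrum_id = id,
                 mass_range = c(0, max(mz) + 1), ...)
}

# a peaklist without going through detection
pl_ <- function(mz, intensity = rep(1, length(mz)), snr = rep(100, length(mz)),
                id = "s") {
  peaklist(mz, intensity, snr, spectrum_id = id)
}

# feature matrix straight from an intensity matrix
fm_ <- function(intensity, ids = paste0("s", seq_len(nrow(intensity))),
                bin_mz = seq_len(ncol(intensity)) * 1000) {
  feature_matrix(bin_mz, ids, intensity)
}

# brute-force O(n*w) oracle for the peak criterion: strict window maximum
# (ties to lower index) AND intensity >= snr * noise
oracle_peaks <- function(y, half_window, snr, noise) {
  n <- length(y)
  idx <- integer(0)
  for (i in seq_len(n)) {
    w <- max(1, i - half_window):min(n, i + half_window)
    lower <- w[w < i]; upper <- w[w > i]
    if (all(y[lower] < y[i]) && all(y[upper] <= y[i]) &&
        y[i] > 0 && (noise == 0 || y[i] >= snr * noise))
      idx <- c(idx, i)
  }
  idx
}

# brute-force morphological opening with clipped windows
oracle_opening <- function(y, h) {
  n <- length(y)
  ero <- sapply(seq_len(n), function(i) min(y[max(1, i - h):min(n, i + h)]))
  sapply(seq_len(n), function(i) max(ero[max(1, i - h):min(n, i + h)]))
}

# brute-force agglomerative clustering (average/complete/single) returning
# merge heights + flat clusters at a cut; small n only
oracle_linkage_cut <- function(D, method, h_cut) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      dd <- D[clusters[[a]], clusters[[b]], drop = FALSE]
      val <- switch(method, average = mean(dd), complete = max(dd),
                    single = min(dd))
      if (val < best[1]) best <- c(val, a, b)
    }
    if (best[1] > h_cut) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
  lab
}

# exhaustive expected distinct-MTU count of a subsample of size m
oracle_rarefy <- function(counts, m) {
  items <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(items), m)
  mean(apply(combs, 2, function(ix) length(unique(items[ix]))))
}

# small cached default synthetic library (built once per test run)
.fixture_env <- new.env()
default_library <- function() {
  if (is.null(.fixture_env$lib))
    .fixture_env$lib <- generate_library(synth_config(seed = 101))
  .fixture_env$lib
}
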