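#' Feature matrix of aligned peak bins
#'
#' Spectra-by-bins intensity matrix with a binary presence mask. Bin centers
#' are strictly ascending; `presence[i, j]` is `intensity[i, j] > 0`.
#'
#' @param bin_mz ascending numeric vector of bin centers (Da).
#' @param spectrum_ids character vector, one per row.
#' @param intensity numeric matrix, `length(spectrum_ids)` rows and
#'   `length(bin_mz)` columns, non-negative (0 = peak absent).
#' @param n_dropped number of same-spectrum duplicate peaks dropped during
#'   binning (bookkeeping for conservation checks).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(bin_mz, spectrum_ids, intensity, n_dropped = 0L) {
  intensity <- as.matrix(intensity)
  if (length(bin_mz) != ncol(intensity) ||
      length(spectrum_ids) != nrow(intensity))
    stop("feature_matrix dimensions disagree", call. = FALSE)
  if (length(bin_mz) > 1 && any(diff(bin_mz) <= 0))
    stop("bin centers must be strictly ascending", call. = FALSE)
  if (length(intensity) && any(intensity < 0))
    stop("bin intensities must be >= 0", call. = FALSE)
  structure(list(bin_mz = as.numeric(bin_mz),
                 spectrum_ids = as.character(spectrum_ids),
                 intensity = intensity,
                 presence = intensity > 0,
                 n_dropped = as.integer(n_dropped)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d spectra x %d bins (%d presences)\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$presence)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensity)

#' Estimate and apply linear mass-drift corrections across peak lists
#'
#' Anchor peaks (SNR at least `align_snr`) are pooled across spectra and
#' grouped within the relative `align_tolerance`; groups present in at least
#' `min_freq` of the spectra become reference peaks. Each spectrum then gets
#' a linear mass correction `mz' = a*mz + b` fitted by least squares on its
#' matched reference peaks and applied to all of its peaks. A spectrum with
#' fewer than 2 reference matches is returned unwarped and flagged in the
#' `warp` attribute of the result.
#'
#' In the full pipeline the anchor peak lists are detected with
#' `align_halfwindow`/`align_snr` and the fitted corrections are then applied
#' to the peak lists detected with `peak_halfwindow`/`peak_snr`; see
#' [align_library()].
#'
#' @param peaklists list of at least 2 [peaklist()] objects.
#' @param align_tolerance relative mass tolerance for matching.
#' @param align_snr minimum SNR for anchor peaks.
#' @param min_freq fraction of spectra a reference peak must appear in
#'   (default 0.9).
#' @return list of warped peak lists; `attr(, "warp")` is a data.frame with
#'   columns `spectrum_id, a, b, n_matched, warped`.
#' @export
warp_peaklists <- function(peaklists, align_tolerance, align_snr,
                           min_freq = 0.9) {
  if (length(peaklists) < 2)
    stop("warping needs at least 2 peak lists", call. = FALSE)
  anchors <- lapply(peaklists, function(pl) pl[pl$snr >= align_snr, , drop = FALSE])
  ref <- reference_peaks(anchors, align_tolerance, min_freq)
  fits <- lapply(seq_along(peaklists), function(i) {
    fit_warp(anchors[[i]], ref, align_tolerance)
  })
  warped <- lapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    f <- fits[[i]]
    if (f$warped && nrow(pl)) pl$mz <- f$a * pl$mz + f$b
    pl
  })
  if (!length(ref))
    warning("no reference peaks found; identity warp applied to all spectra")
  attr(warped, "warp") <- data.frame(
    spectrum_id = vapply(peaklists, attr, "", "spectrum_id"),
    a = vapply(fits, `[[`, 0, "a"), b = vapply(fits, `[[`, 0, "b"),
    n_matched = vapply(fits, `[[`, 0L, "n"),
    warped = vapply(fits, `[[`, FALSE, "warped"))
  attr(warped, "reference_mz") <- ref
  warped
}

# group pooled anchor masses by relative tolerance; return group means that
# occur in >= min_freq of the spectra
reference_peaks <- function(anchors, tolerance, min_freq) {
  n_spec <- length(anchors)
  mz <- unlist(lapply(anchors, `[[`, "mz"))
  who <- rep(seq_len(n_spec), vapply(anchors, nrow, 0L))
  if (!length(mz)) return(numeric(0))
  o <- order(mz); mz <- mz[o]; who <- who[o]
  # split the sorted pooled masses where the gap exceeds the tolerance
  grp <- cumsum(c(1, diff(mz) > tolerance * mz[-length(mz)]))
  means <- tapply(mz, grp, mean)
  freq <- tapply(who, grp, function(w) length(unique(w))) / n_spec
  sort(as.numeric(means[freq >= min_freq]))
}

fit_warp <- function(anchor_pl, ref, tolerance) {
  if (!length(ref) || nrow(anchor_pl) == 0)
    return(list(a = 1, b = 0, n = 0L, warped = FALSE))
  # nearest reference within tolerance for each anchor peak
  idx <- findInterval(anchor_pl$mz, ref)
  cand_lo <- pmax(idx, 1L); cand_hi <- pmin(idx + 1L, length(ref))
  d_lo <- abs(anchor_pl$mz - ref[cand_lo])
  d_hi <- abs(anchor_pl$mz - ref[cand_hi])
  nearest <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
  dist <- pmin(d_lo, d_hi)
  ok <- dist <= tolerance * anchor_pl$mz
  if (sum(ok) < 2) return(list(a = 1, b = 0, n = sum(ok), warped = FALSE))
  x <- anchor_pl$mz[ok]; y <- ref[nearest[ok]]
  fit <- lm.fit(cbind(1, x), y)$coefficients
  list(a = unname(fit[2]), b = unname(fit[1]), n = sum(ok), warped = TRUE)
}

#' Strict binning of warped peak lists into a feature matrix
#'
#' All peaks are pooled and sorted by m/z, then recursively split at the
#' largest gap until (a) every member lies within `tolerance * mean(bin)` of
#' the bin mean and (b) no bin holds two peaks from the same spectrum. When a
#' same-spectrum conflict cannot be split (coincident masses), the more
#' intense peak is kept and the other dropped; drops are counted in the
#' matrix's `n_dropped` field so that
#' `sum(presence) + n_dropped == total input peaks`.
#'
#' @param peaklists list of [peaklist()] objects (typically warped).
#' @param tolerance relative mass tolerance defining a bin.
#' @return a [feature_matrix()]; empty peak lists give a 0-column matrix.
#' @export
bin_peaks <- function(peaklists, tolerance) {
  ids <- vapply(peaklists, attr, "", "spectrum_id")
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids in peak lists", call. = FALSE)
  mz <- unlist(lapply(peaklists, `[[`, "mz"))
  intensity <- unlist(lapply(peaklists, `[[`, "intensity"))
  who <- rep(seq_along(peaklists), vapply(peaklists, nrow, 0L))
  n_spec <- length(peaklists)
  if (!length(mz))
    return(feature_matrix(numeric(0), ids,
                          matrix(0, n_spec, 0)))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; who <- who[o]

  bins <- list(); drops <- 0L
  stack <- list(seq_along(mz))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    m <- mz[seg]
    within_tol <- all(abs(m - mean(m)) <= tolerance * mean(m))
    dup <- anyDuplicated(who[seg]) > 0L
    if ((within_tol && !dup) || length(seg) == 1L) {
      bins[[length(bins) + 1L]] <- seg
      next
    }
    gaps <- diff(m)
    if (max(gaps) <= 0) {
      # coincident masses: resolve same-spectrum duplicates by intensity
      keep <- seg[order(who[seg], -intensity[seg])]
      keep <- keep[!duplicated(who[keep])]
      drops <- drops + length(seg) - length(keep)
      bins[[length(bins) + 1L]] <- keep
      next
    }
    cut <- which.max(gaps)
    stack[[length(stack) + 1L]] <- seg[1:cut]
    stack[[length(stack) + 1L]] <- seg[(cut + 1):length(seg)]
  }
  centers <- vapply(bins, function(s) mean(mz[s]), 0)
  o <- order(centers)
  bins <- bins[o]; centers <- centers[o]
  mat <- matrix(0, n_spec, length(bins))
  for (j in seq_along(bins)) {
    s <- bins[[j]]
    mat[who[s], j] <- intensity[s]
  }
  feature_matrix(centers, ids, mat, n_dropped = drops)
}

#' Preprocess, warp and bin a spectrum library
#'
#' The per-`param_set` alignment stage used by both optimization loops:
#' preprocess each spectrum, detect anchor peaks
#' (`align_halfwindow`/`align_snr`) to fit per-spectrum linear mass
#' corrections, apply the corrections to the peaks detected with
#' `peak_halfwindow`/`peak_snr`, and bin at `align_tolerance`.
#'
#' @param spectra list of [maldi_spectrum()] objects.
#' @param params a [param_set()].
#' @param min_freq reference-peak frequency cutoff (default 0.9).
#' @return a [feature_matrix()]; `attr(, "peaklists")` holds the warped peak
#'   lists.
#' @export
align_library <- function(spectra, params, min_freq = 0.9) {
  profiles <- lapply(spectra, preprocess_profile, params = params)
  anchors <- lapply(profiles, detect_peaks,
                    half_window = params$align_halfwindow,
                    snr = params$align_snr)
  peaks <- lapply(profiles, detect_peaks,
                  half_window = params$peak_halfwindow,
                  snr = params$peak_snr)
  if (length(spectra) >= 2) {
    ref <- reference_peaks(anchors, params$align_tolerance, min_freq)
    peaks <- lapply(seq_along(peaks), function(i) {
      f <- fit_warp(anchors[[i]], ref, params$align_tolerance)
      pl <- peaks[[i]]
      if (f$warped && nrow(pl)) pl$mz <- f$a * pl$mz + f$b
      pl
    })
  }
  fm <- bin_peaks(peaks, params$align_tolerance)
  attr(fm, "peaklists") <- peaks
  fm
}
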