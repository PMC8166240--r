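#' Savitzky-Golay smoothing
#'
#' Single-pass Savitzky-Golay filter of window `2*half_window + 1` points and
#' polynomial order 3 (an order-3 filter reproduces cubic trends exactly).
#' Edge points are fitted with asymmetric windows so the filter remains exact
#' on polynomials up to the boundary. Negative outputs are clipped to zero to
#' preserve the spectrum invariant.
#'
#' @param spectrum a [maldi_spectrum()].
#' @param half_window half-window in grid points, at least 2 (an order-3 fit
#'   needs at least 4 points).
#' @return smoothed spectrum on the same m/z grid.
#' @export
smooth_spectrum <- function(spectrum, half_window) {
  stopifnot(is_spectrum(spectrum))
  h <- as.integer(half_window)
  n <- length(spectrum$mz)
  if (h < 2) stop("smoothing half_window must be >= 2", call. = FALSE)
  if (2L * h + 1L > n)
    stop("smoothing window (", 2L * h + 1L, ") longer than spectrum (", n, ")",
         call. = FALSE)
  y <- spectrum$intensity
  w <- savgol_coef(h)
  sm <- as.numeric(stats::filter(y, rev(w), sides = 2))
  # asymmetric least-squares fits at the two edges
  for (i in seq_len(h)) {
    sm[i] <- savgol_edge(y[1:(2 * h + 1)], i)
    sm[n - i + 1] <- savgol_edge(rev(y[(n - 2 * h):n]), i)
  }
  out <- spectrum
  out$intensity <- pmax(sm, 0)
  out
}

# central Savitzky-Golay weights, order 3, window 2h+1
savgol_coef <- function(h) {
  x <- seq(-h, h)
  A <- outer(x, 0:3, `^`)
  (solve(crossprod(A), t(A)))[1, ]
}

# order-3 LS fit on the first 2h+1 points, evaluated at point i (1-based)
savgol_edge <- function(y, i) {
  x <- seq_along(y) - i
  A <- outer(x, 0:3, `^`)
  as.numeric((solve(crossprod(A), crossprod(A, y)))[1])
}

#' Top-hat baseline subtraction
#'
#' The baseline is the morphological opening of the intensity vector (erosion
#' followed by dilation with a flat structuring element of
#' `2*half_window + 1` points); the top-hat transform subtracts it. Opening
#' is idempotent, so applying the operation twice equals applying it once.
#'
#' @inheritParams smooth_spectrum
#' @param half_window structuring-element half-width in grid points.
#' @return baseline-subtracted spectrum (all intensities >= 0).
#' @export
subtract_baseline <- function(spectrum, half_window) {
  stopifnot(is_spectrum(spectrum))
  h <- as.integer(half_window)
  n <- length(spectrum$mz)
  if (h < 1) stop("baseline half_window must be >= 1", call. = FALSE)
  if (2L * h + 1L > n)
    stop("baseline window longer than spectrum", call. = FALSE)
  baseline <- .running_max(.running_min(spectrum$intensity, h), h)
  out <- spectrum
  out$intensity <- pmax(spectrum$intensity - baseline, 0)
  out
}

#' Total-ion-current normalization
#'
#' Divides intensities by their sum so the spectrum integrates to 1. Applied
#' before peak detection so that binned intensities feeding the cosine
#' similarity are on a common scale across spectra.
#'
#' @inheritParams smooth_spectrum
#' @return normalized spectrum; intensities sum to 1.
#' @export
normalize_tic <- function(spectrum) {
  stopifnot(is_spectrum(spectrum))
  tot <- sum(spectrum$intensity)
  if (tot <= 0) stop("cannot TIC-normalize an all-zero spectrum", call. = FALSE)
  out <- spectrum
  out$intensity <- spectrum$intensity / tot
  out
}

#' Robust noise level of a spectrum
#'
#' `1.4826 * median(|intensity - median(intensity)|)`: the scaled median
#' absolute deviation, consistent for the standard deviation under Gaussian
#' noise and insensitive to isolated peaks.
#'
#' @inheritParams smooth_spectrum
#' @return scalar noise level in intensity units.
#' @export
estimate_noise <- function(spectrum) {
  stopifnot(is_spectrum(spectrum))
  if (length(spectrum$mz) < 10)
    stop("need >= 10 points to estimate noise", call. = FALSE)
  mad(spectrum$intensity, constant = 1.4826)
}

#' SNR-gated local-maximum peak detection
#'
#' A grid point is reported as a peak iff it is the maximum within
#' `half_window` points on either side (ties broken toward lower m/z) and its
#' intensity is at least `snr` times the spectrum's noise level
#' ([estimate_noise()]). Expected input is a smoothed, baseline-subtracted
#' spectrum. If the noise estimate is exactly zero while signal is present,
#' peaks are returned with `snr = Inf` and the peak list carries
#' `attr(,"zero_noise") = TRUE`.
#'
#' @inheritParams smooth_spectrum
#' @param half_window detection half-window in grid points.
#' @param snr minimum signal-to-noise ratio.
#' @return a [peaklist()].
#' @export
detect_peaks <- function(spectrum, half_window, snr) {
  stopifnot(is_spectrum(spectrum))
  h <- as.integer(half_window)
  if (h < 1) stop("peak half_window must be >= 1", call. = FALSE)
  y <- spectrum$intensity
  noise <- estimate_noise(spectrum)
  idx <- .local_maxima(y, h)
  idx <- idx[y[idx] > 0]
  if (noise > 0) {
    idx <- idx[y[idx] >= snr * noise]
    snrs <- y[idx] / noise
    zero_noise <- FALSE
  } else {
    snrs <- rep(Inf, length(idx))
    zero_noise <- TRUE
  }
  pl <- peaklist(mz = spectrum$mz[idx], intensity = y[idx], snr = snrs,
                 spectrum_id = spectrum$spectrum_id, noise = noise)
  attr(pl, "zero_noise") <- zero_noise
  pl
}

#' Average replicate spectra
#'
#' Pointwise mean intensity on the grid of the first spectrum; spectra on
#' different grids are linearly interpolated onto it first. Used for the
#' replicate BTS spots on each target and, optionally, replicate isolate
#' spots.
#'
#' @param spectra non-empty list of [maldi_spectrum()] objects.
#' @param spectrum_id id for the averaged spectrum; default concatenates the
#'   source ids.
#' @return a [maldi_spectrum()]; provenance fields taken from the first input.
#' @export
average_replicates <- function(spectra, spectrum_id = NULL) {
  if (!length(spectra)) stop("no spectra to average", call. = FALSE)
  stopifnot(all(vapply(spectra, is_spectrum, logical(1))))
  ref <- spectra[[1]]
  ints <- vapply(spectra, function(s) {
    if (isTRUE(all.equal(s$mz, ref$mz))) s$intensity
    else approx(s$mz, s$intensity, xout = ref$mz, rule = 2)$y
  }, numeric(length(ref$mz)))
  out <- ref
  out$intensity <- rowMeans(ints)
  out$spectrum_id <- spectrum_id %||%
    paste(vapply(spectra, `[[`, "", "spectrum_id"), collapse = "+")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the fixed profile-preprocessing chain on one spectrum
#'
#' smooth -> subtract_baseline -> normalize_tic; the order is fixed.
#'
#' @param spectrum a [maldi_spectrum()].
#' @param params a [param_set()].
#' @return the processed profile spectrum.
#' @export
preprocess_profile <- function(spectrum, params) {
  s <- smooth_spectrum(spectrum, params$smooth_halfwindow)
  s <- subtract_baseline(s, params$baseline_halfwindow)
  normalize_tic(s)
}

#' Preprocess and detect peaks in one call
#'
#' [preprocess_profile()] followed by [detect_peaks()].
#'
#' @inheritParams preprocess_profile
#' @param detect_with `"peak"` uses `peak_halfwindow`/`peak_snr`; `"align"`
#'   uses `align_halfwindow`/`align_snr` (anchor peaks for warping).
#' @return a [peaklist()].
#' @export
preprocess_spectrum <- function(spectrum, params,
                                detect_with = c("peak", "align")) {
  detect_with <- match.arg(detect_with)
  s <- preprocess_profile(spectrum, params)
  if (detect_with == "peak")
    detect_peaks(s, params$peak_halfwindow, params$peak_snr)
  else
    detect_peaks(s, params$align_halfwindow, params$align_snr)
}
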