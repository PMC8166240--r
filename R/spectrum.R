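#' Construct a MALDI-TOF profile spectrum
#'
#' A `maldi_spectrum` holds one profile mass spectrum: an m/z axis in Daltons,
#' strictly ascending, and a non-negative intensity vector of the same length,
#' plus acquisition provenance (isolate, replicate spot group, target plate).
#' Out-of-order rows are sorted and duplicate m/z values are collapsed by
#' summing their intensities, so constructor output always satisfies the
#' class invariants regardless of input order.
#'
#' @param mz numeric vector of m/z values (Da).
#' @param intensity numeric vector of intensities, same length as `mz`.
#' @param spectrum_id character scalar identifying this spectrum.
#' @param isolate_id isolate the spectrum was acquired from.
#' @param group one of `"isolate"`, `"bts_reference"`, `"blank"`. BTS is the
#'   bacterial test standard spotted on every target plate.
#' @param target_id identifier of the MALDI target plate; spectra from
#'   different targets show systematic mass drift.
#' @param mass_range declared acquisition range in Da; m/z outside it is an
#'   error. Default 1880--20000 Da (linear low-mass protein window).
#' @return an object of class `maldi_spectrum`.
#' @export
maldi_spectrum <- function(mz, intensity, spectrum_id = "spectrum",
                           isolate_id = spectrum_id,
                           group = c("isolate", "bts_reference", "blank"),
                           target_id = "T1",
                           mass_range = c(1880, 20000)) {
  group <- match.arg(group)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (anyNA(mz) || anyNA(intensity))
    stop("mz/intensity must not contain NA", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  if (length(mz) < 2)
    stop("a spectrum needs at least 2 distinct points", call. = FALSE)
  if (any(intensity < 0))
    stop("negative intensities in spectrum '", spectrum_id, "'", call. = FALSE)
  if (mz[1] < mass_range[1] || mz[length(mz)] > mass_range[2])
    stop("m/z outside the declared acquisition range [",
         mass_range[1], ", ", mass_range[2], "] in '", spectrum_id, "'",
         call. = FALSE)
  structure(
    list(spectrum_id = as.character(spectrum_id),
         isolate_id = as.character(isolate_id),
         group = group, target_id = as.character(target_id),
         mz = mz, intensity = intensity, mass_range = mass_range),
    class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum> %s (%s, %s, target %s): %d points, m/z %.1f-%.1f\n",
              x$spectrum_id, x$isolate_id, x$group, x$target_id,
              length(x$mz), x$mz[1], x$mz[length(x$mz)]))
  invisible(x)
}

#' @export
length.maldi_spectrum <- function(x) length(x$mz)

is_spectrum <- function(x) inherits(x, "maldi_spectrum")

#' Construct a peak list
#'
#' Detected peaks for one spectrum: m/z, intensity and signal-to-noise ratio,
#' kept sorted by ascending m/z.
#'
#' @param mz,intensity,snr numeric vectors of equal length; intensities must
#'   be positive, SNR non-negative (may be `Inf` when the noise estimate is
#'   exactly zero; see [detect_peaks()]).
#' @param spectrum_id id of the parent spectrum.
#' @param noise the noise level the SNRs were computed against.
#' @return an object of class `peaklist` (a data.frame with attributes).
#' @export
peaklist <- function(mz, intensity, snr, spectrum_id = "spectrum",
                     noise = NA_real_) {
  if (!(length(mz) == length(intensity) && length(mz) == length(snr)))
    stop("peaklist fields must have equal length", call. = FALSE)
  o <- order(mz)
  df <- data.frame(mz = as.numeric(mz)[o],
                   intensity = as.numeric(intensity)[o],
                   snr = as.numeric(snr)[o])
  if (nrow(df) && any(df$intensity <= 0))
    stop("peak intensities must be > 0", call. = FALSE)
  if (nrow(df) && any(df$snr < 0))
    stop("peak snr must be >= 0", call. = FALSE)
  structure(df, spectrum_id = as.character(spectrum_id),
            noise = noise, class = c("peaklist", "data.frame"))
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %s: %d peaks\n", attr(x, "spectrum_id"), nrow(x)))
  if (nrow(x)) print.data.frame(head(x, 10))
  invisible(x)
}

#' The seven tunable preprocessing/alignment parameters
#'
#' Half-windows are in grid points; `align_tolerance` is a relative mass
#' tolerance (e.g. 0.002 = 2000 ppm); SNR thresholds are dimensionless.
#'
#' @param smooth_halfwindow Savitzky-Golay half-window (points).
#' @param baseline_halfwindow top-hat structuring-element half-window (points).
#' @param align_halfwindow peak-detection half-window used to build the
#'   alignment anchor peak lists (points).
#' @param align_tolerance relative tolerance for matching anchor peaks.
#' @param align_snr minimum SNR for a peak to serve as an alignment anchor.
#' @param peak_halfwindow peak-detection half-window (points).
#' @param peak_snr minimum SNR for a reported peak.
#' @return an object of class `param_set`.
#' @export
param_set <- function(smooth_halfwindow = 10, baseline_halfwindow = 75,
                      align_halfwindow = 20, align_tolerance = 0.002,
                      align_snr = 10, peak_halfwindow = 20, peak_snr = 10) {
  p <- list(smooth_halfwindow = as.integer(smooth_halfwindow),
            baseline_halfwindow = as.integer(baseline_halfwindow),
            align_halfwindow = as.integer(align_halfwindow),
            align_tolerance = as.numeric(align_tolerance),
            align_snr = as.numeric(align_snr),
            peak_halfwindow = as.integer(peak_halfwindow),
            peak_snr = as.numeric(peak_snr))
  hw <- c(p$smooth_halfwindow, p$baseline_halfwindow, p$align_halfwindow,
          p$peak_halfwindow)
  if (any(hw < 1L)) stop("half-windows must be >= 1", call. = FALSE)
  if (p$align_tolerance <= 0) stop("align_tolerance must be > 0", call. = FALSE)
  if (p$align_snr <= 0 || p$peak_snr <= 0)
    stop("SNR thresholds must be > 0", call. = FALSE)
  structure(p, class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
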