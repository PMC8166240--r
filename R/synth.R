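#' Configuration for the synthetic MALDI-TOF library generator
#'
#' The generator emulates linear-mode protein fingerprints over the
#' instrument's low-mass window: each species has a template of
#' `peaks_per_species` peaks (uniform masses, log-normal intensities);
#' strains of a species keep `shared_peak_fraction` of the template
#' (always including the top third by intensity) and replace the rest with
#' minor private peaks; a fraction `between_shared_fraction` of every
#' template consists of conserved masses common to all species (dominant
#' and intensity-correlated, like the major ribosomal proteins), so
#' unrelated species share a few peaks and near-zero-Jaccard pairs retain a
#' non-trivial cosine similarity.
#' Spectra are rendered as Gaussian peaks (sd `peak_sigma` Da) on a regular
#' grid, plus an exponentially decaying baseline (decay ~2 kDa, as chemical
#' matrix background) and iid Gaussian noise; spectra on target plate k get
#' a multiplicative mass drift of `(k - (K+1)/2) * target_drift`.
#'
#' @param n_species,strains_per_species library layout (default 20 x 3).
#' @param peaks_per_species template size (default 30).
#' @param shared_peak_fraction within-species template retention (default 0.9).
#' @param between_shared_fraction fraction of each template that is
#'   conserved across all species (default 0.1).
#' @param mass_range acquisition window in Da (default 1880--20000).
#' @param peak_sigma rendered peak width in Da (default 3).
#' @param target_drift relative mass drift between adjacent targets
#'   (default 5e-4).
#' @param noise_sd Gaussian noise sd in intensity units (default 1).
#' @param baseline_amplitude baseline height at the low-mass edge
#'   (default 20).
#' @param amp_meanlog,amp_sdlog log-normal peak-amplitude parameters
#'   (default meanlog log(50), sdlog 0.7: median 50, i.e. median SNR ~50
#'   over unit noise, ~20-fold 95% dynamic range).
#' @param grid_step m/z grid spacing in Da (default 1).
#' @param bts_n_peaks bacterial-test-standard template size (default 21).
#' @param within_identity,between_identity 16S percent identity assigned to
#'   same-species / different-species isolate pairs (99.5 +/- 0.3 and
#'   85 +/- 3, clipped to \[70, 100\]).
#' @param seed integer seed making the whole library reproducible.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_species = 20, strains_per_species = 3,
                         peaks_per_species = 30,
                         shared_peak_fraction = 0.9,
                         between_shared_fraction = 0.1,
                         mass_range = c(1880, 20000),
                         peak_sigma = 3, target_drift = 5e-4,
                         noise_sd = 1, baseline_amplitude = 20,
                         amp_meanlog = log(50), amp_sdlog = 0.7,
                         grid_step = 1, bts_n_peaks = 21,
                         within_identity = 99.5, between_identity = 85,
                         seed = 1) {
  cfg <- as.list(environment())
  if (cfg$shared_peak_fraction < 0 || cfg$shared_peak_fraction > 1 ||
      cfg$between_shared_fraction < 0 || cfg$between_shared_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$n_species < 1 || cfg$strains_per_species < 1 ||
      cfg$peaks_per_species < 1)
    stop("counts must be >= 1", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# render a peak template (masses, amplitudes) onto the grid
render_spectrum <- function(masses, amps, cfg, drift = 0, noise_sd = NULL) {
  grid <- seq(cfg$mass_range[1], cfg$mass_range[2], by = cfg$grid_step)
  y <- numeric(length(grid))
  m_eff <- masses * (1 + drift)
  for (k in seq_along(m_eff)) {
    lo <- max(1L, ceiling((m_eff[k] - 8 * cfg$peak_sigma - grid[1]) / cfg$grid_step) + 1L)
    hi <- min(length(grid), floor((m_eff[k] + 8 * cfg$peak_sigma - grid[1]) / cfg$grid_step) + 1L)
    if (lo > hi) next
    w <- lo:hi
    y[w] <- y[w] + amps[k] * exp(-(grid[w] - m_eff[k])^2 / (2 * cfg$peak_sigma^2))
  }
  baseline <- cfg$baseline_amplitude * exp(-(grid - grid[1]) / 2000)
  nsd <- noise_sd %||% cfg$noise_sd
  y <- y + baseline + if (nsd > 0) rnorm(length(grid), 0, nsd) else 0
  list(mz = grid, intensity = pmax(y, 0))
}

draw_masses <- function(n, cfg) {
  runif(n, cfg$mass_range[1] + 150, cfg$mass_range[2] - 150)
}

#' Generate a synthetic isolate library with ground truth
#'
#' Produces one spectrum per strain (isolate), spread across `n_targets`
#' plates, a truth table with the generating species labels, and a matching
#' synthetic 16S identity matrix keyed by isolate id. Optionally plants
#' deliberately degraded spectra for exercising the quality-control filter:
#' `degrade_snr` isolates get peak amplitudes rescaled to a median of 1.5x
#' the noise level (far below a median-SNR-15 gate) and `degrade_peaks`
#' isolates get templates truncated to 6 peaks (below a 13-peak gate).
#'
#' @param cfg a [synth_config()].
#' @param n_targets number of target plates (default 2).
#' @param degrade_snr,degrade_peaks how many isolates to degrade (default 0).
#' @return list of class `synth_library`: `spectra` (list of
#'   [maldi_spectrum()]), `truth` (data.frame `spectrum_id, isolate_id,
#'   species, target_id, degraded`), `identity` ([identity_matrix()]),
#'   `cfg`.
#' @export
generate_library <- function(cfg = synth_config(), n_targets = 2,
                             degrade_snr = 0, degrade_peaks = 0) {
  set.seed(cfg$seed)
  n_iso <- cfg$n_species * cfg$strains_per_species
  if (degrade_snr + degrade_peaks > n_iso)
    stop("more degraded isolates than isolates", call. = FALSE)
  n_cons <- round(cfg$between_shared_fraction * cfg$peaks_per_species)
  conserved <- runif(n_cons, cfg$mass_range[1] + 150, cfg$mass_range[2] - 150)
  # conserved peaks are dominant and intensity-correlated across species, as
  # the major ribosomal proteins are in linear-mode fingerprints; this keeps
  # near-zero-Jaccard pairs at a non-trivial cosine similarity
  cons_amp <- 2 * rlnorm(n_cons, cfg$amp_meanlog, 0.5)
  templates <- lapply(seq_len(cfg$n_species), function(s) {
    list(mass = c(conserved,
                  draw_masses(cfg$peaks_per_species - n_cons, cfg)),
         amp = c(cons_amp * rlnorm(n_cons, 0, 0.3),
                 rlnorm(cfg$peaks_per_species - n_cons, cfg$amp_meanlog,
                        cfg$amp_sdlog)))
  })
  degraded <- rep("none", n_iso)
  if (degrade_snr + degrade_peaks > 0) {
    idx <- sample.int(n_iso, degrade_snr + degrade_peaks)
    degraded[idx[seq_len(degrade_snr)]] <- "snr"
    if (degrade_peaks > 0)
      degraded[idx[degrade_snr + seq_len(degrade_peaks)]] <- "peaks"
  }
  drift_of <- function(k) cfg$target_drift * (k - (n_targets + 1) / 2)
  spectra <- vector("list", n_iso)
  truth <- vector("list", n_iso)
  i <- 0L
  for (s in seq_len(cfg$n_species)) for (st in seq_len(cfg$strains_per_species)) {
    i <- i + 1L
    tmpl <- templates[[s]]
    n_keep <- round(cfg$shared_peak_fraction * cfg$peaks_per_species)
    # strain variation affects the minor peaks: the top third of the
    # template by intensity is always retained
    rk <- rank(-tmpl$amp, ties.method = "first")
    core <- which(rk <= ceiling(cfg$peaks_per_species / 3))
    n_extra <- max(0L, n_keep - length(core))
    keep <- c(core, sample(setdiff(seq_len(cfg$peaks_per_species), core),
                           n_extra))
    mass <- c(tmpl$mass[keep],
              draw_masses(cfg$peaks_per_species - n_keep, cfg))
    # strain-private peaks are characteristically minor: half amplitude
    amp <- c(tmpl$amp[keep] * rlnorm(n_keep, 0, 0.2),
             0.5 * rlnorm(cfg$peaks_per_species - n_keep, cfg$amp_meanlog,
                          cfg$amp_sdlog))
    if (degraded[i] == "snr") amp <- amp / median(amp) * 1.5 * cfg$noise_sd
    if (degraded[i] == "peaks") { mass <- mass[1:6]; amp <- amp[1:6] }
    tgt <- ((i - 1L) %% n_targets) + 1L
    xy <- render_spectrum(mass, amp, cfg, drift = drift_of(tgt))
    iso_id <- sprintf("iso%03d", i)
    spectra[[i]] <- maldi_spectrum(xy$mz, xy$intensity,
                                   spectrum_id = iso_id, isolate_id = iso_id,
                                   group = "isolate",
                                   target_id = paste0("T", tgt),
                                   mass_range = cfg$mass_range)
    truth[[i]] <- data.frame(spectrum_id = iso_id, isolate_id = iso_id,
                             species = sprintf("sp%02d", s),
                             target_id = paste0("T", tgt),
                             degraded = degraded[i])
  }
  truth <- do.call(rbind, truth)
  ident <- synth_identity(truth$isolate_id, truth$species, cfg)
  structure(list(spectra = spectra, truth = truth, identity = ident,
                 templates = templates, cfg = cfg),
            class = "synth_library")
}

synth_identity <- function(ids, species, cfg) {
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- if (species[i] == species[j])
      cfg$within_identity + runif(1, -0.3, 0.3)
    else cfg$between_identity + runif(1, -3, 3)
    v <- min(max(v, 70), 100)
    m[i, j] <- v; m[j, i] <- v
  }
  identity_matrix(m)
}

#' @export
print.synth_library <- function(x, ...) {
  cat(sprintf("<synth_library> %d spectra (%d species x %d strains), seed %d\n",
              length(x$spectra), x$cfg$n_species, x$cfg$strains_per_species,
              x$cfg$seed))
  invisible(x)
}

#' Generate replicate bacterial-test-standard spectra
#'
#' One fixed template of `cfg$bts_n_peaks` peaks is rendered on every
#' target with the target's mass drift and fresh per-replicate noise.
#' `perturb_da` shifts the highest-mass template peak by that many Daltons
#' on every target except the first — a controlled way to make exactly one
#' peak fall outside a binning tolerance between targets.
#'
#' @param cfg a [synth_config()].
#' @param n_targets target plates (default 2).
#' @param replicates_per_target BTS spots per target (default 2).
#' @param perturb_da mass perturbation in Da (default 0).
#' @param drop_peak omit the highest-mass template peak on targets after the
#'   first, so per-target peak sets share 20 of a 21-peak union.
#' @return list of [maldi_spectrum()] with `group = "bts_reference"`.
#' @export
generate_bts <- function(cfg = synth_config(), n_targets = 2,
                         replicates_per_target = 2, perturb_da = 0,
                         drop_peak = FALSE) {
  set.seed(cfg$seed + 10000L)
  # stratified masses: one peak per equal-width stratum, jittered within its
  # central 60%, so calibrant peaks are always well separated
  lo <- cfg$mass_range[1] + 150; hi <- cfg$mass_range[2] - 150
  width <- (hi - lo) / cfg$bts_n_peaks
  mass <- lo + (seq_len(cfg$bts_n_peaks) - 1) * width +
    runif(cfg$bts_n_peaks, 0.2 * width, 0.8 * width)
  amp <- rlnorm(cfg$bts_n_peaks, cfg$amp_meanlog, cfg$amp_sdlog)
  drift_of <- function(k) cfg$target_drift * (k - (n_targets + 1) / 2)
  out <- list()
  for (k in seq_len(n_targets)) {
    m_k <- mass; a_k <- amp
    if (perturb_da != 0 && k > 1)
      m_k[length(m_k)] <- m_k[length(m_k)] + perturb_da
    if (drop_peak && k > 1) {
      m_k <- m_k[-length(m_k)]; a_k <- a_k[-length(a_k)]
    }
    for (r in seq_len(replicates_per_target)) {
      xy <- render_spectrum(m_k, a_k, cfg, drift = drift_of(k))
      sid <- sprintf("BTS_T%d_r%d", k, r)
      out[[sid]] <- maldi_spectrum(xy$mz, xy$intensity, spectrum_id = sid,
                                   isolate_id = "BTS",
                                   group = "bts_reference",
                                   target_id = paste0("T", k),
                                   mass_range = cfg$mass_range)
    }
  }
  unname(out)
}

#' Write a synthetic library to disk as plain-text inputs
#'
#' Writes one two-column CSV per spectrum plus `metadata.csv`,
#' `identity.csv` and `truth.csv`, i.e. a complete input set for the
#' file-based pipeline entry points.
#'
#' @param lib a [generate_library()] result.
#' @param dir output directory (created if needed).
#' @param bts optional list from [generate_bts()] to include.
#' @return the directory path, invisibly.
#' @export
write_synth_library <- function(lib, dir, bts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_spectra <- c(lib$spectra, bts)
  meta <- do.call(rbind, lapply(all_spectra, function(s)
    data.frame(spectrum_id = s$spectrum_id, isolate_id = s$isolate_id,
               group = s$group, target_id = s$target_id)))
  for (s in all_spectra)
    write_spectrum(s, file.path(dir, paste0(s$spectrum_id, ".csv")))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE,
            quote = FALSE)
  write_table(unclass(lib$identity), file.path(dir, "identity.csv"))
  write.csv(lib$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
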