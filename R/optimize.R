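#' Sampling ranges for the seven tunable parameters
#'
#' Integer half-windows are sampled uniformly on integers, SNR thresholds
#' uniformly, and the alignment tolerance log-uniformly (it spans two orders
#' of magnitude). Defaults bracket the conventional settings for linear-mode
#' protein spectra on a ~1 Da grid.
#'
#' @param smooth_halfwindow,baseline_halfwindow,align_halfwindow,peak_halfwindow
#'   integer `(low, high)` bounds in grid points.
#' @param align_tolerance relative-tolerance bounds, sampled log-uniformly.
#' @param align_snr,peak_snr SNR bounds.
#' @return an object of class `param_ranges`.
#' @export
param_ranges <- function(smooth_halfwindow = c(2, 25),
                         baseline_halfwindow = c(10, 200),
                         align_halfwindow = c(5, 50),
                         align_tolerance = c(2e-4, 1e-2),
                         align_snr = c(1, 10),
                         peak_halfwindow = c(5, 50),
                         peak_snr = c(1, 10)) {
  r <- list(smooth_halfwindow = smooth_halfwindow,
            baseline_halfwindow = baseline_halfwindow,
            align_halfwindow = align_halfwindow,
            align_tolerance = align_tolerance,
            align_snr = align_snr,
            peak_halfwindow = peak_halfwindow,
            peak_snr = peak_snr)
  for (nm in names(r)) {
    b <- r[[nm]]
    if (length(b) != 2 || any(b <= 0) || b[1] > b[2])
      stop("invalid bounds for ", nm, call. = FALSE)
  }
  structure(r, class = "param_ranges")
}

#' Draw one random parameter set
#'
#' @param ranges a [param_ranges()].
#' @param rng_seed optional seed; when given, the draw is a pure function of
#'   `(ranges, rng_seed)`. When `NULL`, the current RNG stream is used (the
#'   search loops seed once and draw repeatedly).
#' @return a [param_set()].
#' @export
sample_params <- function(ranges, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ri <- function(b) if (b[1] >= b[2]) as.integer(b[1]) else
    sample(seq.int(ceiling(b[1]), floor(b[2])), 1L)
  ru <- function(b) runif(1, b[1], b[2])
  rlog <- function(b) exp(runif(1, log(b[1]), log(b[2])))
  param_set(smooth_halfwindow = max(2L, ri(ranges$smooth_halfwindow)),
            baseline_halfwindow = ri(ranges$baseline_halfwindow),
            align_halfwindow = ri(ranges$align_halfwindow),
            align_tolerance = rlog(ranges$align_tolerance),
            align_snr = ru(ranges$align_snr),
            peak_halfwindow = ri(ranges$peak_halfwindow),
            peak_snr = ru(ranges$peak_snr))
}

#' Loop-1 objective: BTS reproducibility across targets
#'
#' Replicate bacterial-test-standard (BTS) spectra are averaged per target
#' plate, preprocessed and aligned with the candidate parameters, and the
#' mean pairwise Jaccard coefficient between the per-target average BTS peak
#' sets is returned, together with the shared-peak count of the best pair
#' and the total number of bins. Any failure inside the chain (degenerate
#' parameters) scores 0 with `failed = TRUE` so a random search can continue.
#'
#' @param bts_spectra list of [maldi_spectrum()] with `group ==
#'   "bts_reference"`, at least 2 distinct `target_id`s.
#' @param params a [param_set()].
#' @return list `mean_jaccard`, `shared_peaks`, `total_bins`, `failed`.
#' @export
objective_bts <- function(bts_spectra, params) {
  targets <- split(bts_spectra,
                   vapply(bts_spectra, `[[`, "", "target_id"))
  if (length(targets) < 2)
    stop("need BTS spectra on >= 2 targets", call. = FALSE)
  tryCatch({
    avg <- lapply(names(targets), function(tn)
      average_replicates(targets[[tn]], spectrum_id = paste0("BTS_", tn)))
    fm <- align_library(avg, params)
    if (ncol(fm$intensity) == 0)
      return(list(mean_jaccard = 0, shared_peaks = 0L,
                  total_bins = 0L, failed = TRUE))
    J <- jaccard_matrix(fm)
    shared <- tcrossprod(fm$presence * 1)
    ut <- upper.tri(J)
    best <- which(J == max(J[ut]) & ut, arr.ind = TRUE)[1, ]
    list(mean_jaccard = mean(J[ut]),
         shared_peaks = as.integer(shared[best[1], best[2]]),
         total_bins = ncol(fm$intensity),
         failed = FALSE)
  }, error = function(e)
    list(mean_jaccard = 0, shared_peaks = 0L, total_bins = 0L, failed = TRUE))
}

#' Random-search loop 1: maximize BTS peak reproducibility
#'
#' Draws `n_iter` parameter sets and keeps the one with the highest mean
#' BTS Jaccard; ties broken by higher shared-peak count, then by lower
#' iteration index. Fully reproducible given `seed`.
#'
#' @param spectra spectrum library; only `group == "bts_reference"` entries
#'   are used.
#' @param ranges a [param_ranges()].
#' @param n_iter number of random draws.
#' @param seed integer RNG seed.
#' @return list `trace` (one data.frame row per iteration) and `best`
#'   ([param_set()]).
#' @export
run_loop1 <- function(spectra, ranges = param_ranges(), n_iter = 2000,
                      seed = 1) {
  bts <- Filter(function(s) s$group == "bts_reference", spectra)
  set.seed(seed)
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    p <- sample_params(ranges)
    obj <- objective_bts(bts, p)
    rows[[i]] <- cbind(data.frame(iteration = i),
                       as.data.frame(unclass(p)),
                       data.frame(mean_jaccard = obj$mean_jaccard,
                                  shared_peaks = obj$shared_peaks,
                                  total_bins = obj$total_bins,
                                  failed = obj$failed))
  }
  trace <- do.call(rbind, rows)
  o <- order(-trace$mean_jaccard, -trace$shared_peaks, trace$iteration)
  best <- trace[o[1], ]
  list(trace = trace, best = trace_row_params(best))
}

trace_row_params <- function(row) {
  param_set(smooth_halfwindow = row$smooth_halfwindow,
            baseline_halfwindow = row$baseline_halfwindow,
            align_halfwindow = row$align_halfwindow,
            align_tolerance = row$align_tolerance,
            align_snr = row$align_snr,
            peak_halfwindow = row$peak_halfwindow,
            peak_snr = row$peak_snr)
}

#' SNR/peak-count quality-control filter
#'
#' A spectrum passes iff the median SNR of its `top_k` most intense peaks is
#' at least `snr_threshold` and it has at least `min_peaks` peaks. Spectra
#' with fewer than `top_k` peaks use the median over all their peaks; an
#' empty peak list fails. The decision depends only on the spectrum's own
#' peak list.
#'
#' @param peaklists list of [peaklist()] built with the loop-1 parameters.
#' @param snr_threshold minimum median SNR of the top peaks (default 15).
#' @param top_k how many of the most intense peaks enter the median
#'   (default 10).
#' @param min_peaks minimum number of detected peaks (default 13).
#' @return data.frame of class `qc_report`: `spectrum_id, n_peaks,
#'   median_snr_top10, passed`.
#' @export
qc_filter <- function(peaklists, snr_threshold = 15, top_k = 10,
                      min_peaks = 13) {
  rows <- lapply(peaklists, function(pl) {
    n <- nrow(pl)
    med <- if (n == 0) 0 else {
      top <- pl$snr[order(-pl$intensity)][seq_len(min(top_k, n))]
      median(top)
    }
    data.frame(spectrum_id = attr(pl, "spectrum_id"), n_peaks = n,
               median_snr_top10 = med,
               passed = (med >= snr_threshold) && (n >= min_peaks))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Loop-2 objective: class overlap of similarity values
#'
#' Pairs of isolates are labelled "within" (16S identity at least `cutoff`,
#' default 99%) or "between"; the objective is the balanced
#' misclassification rate minimized over all similarity thresholds `t`:
#' `min_t [P(within < t) + P(between >= t)] / 2`. 0 means the two
#' distributions are perfectly separated; 0.5 means indistinguishable. The
#' value is invariant under strictly monotone transforms of the similarity.
#'
#' @param S similarity matrix (cosine or weighted) with spectrum-id dimnames.
#' @param labels logical matrix, same shape: `TRUE` = within-pair (identity
#'   >= cutoff). Build with [pair_labels()].
#' @return scalar overlap in \[0, 0.5\].
#' @export
objective_discrimination <- function(S, labels) {
  ut <- upper.tri(S)
  overlap_metric(S[ut & labels], S[ut & !labels])
}

#' @param within,between similarity values of within-class and between-class
#'   pairs.
#' @rdname objective_discrimination
#' @export
overlap_metric <- function(within, between) {
  if (!length(within)) stop("no within-class pairs", call. = FALSE)
  if (!length(between)) stop("no between-class pairs", call. = FALSE)
  u <- sort(unique(c(within, between)))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  ov <- vapply(cand, function(t)
    (mean(within < t) + mean(between >= t)) / 2, 0)
  min(ov)
}

#' Within/between pair labels from a 16S identity matrix
#'
#' @param identity an [identity_matrix()].
#' @param ids spectrum/isolate ids giving the order of the similarity-matrix
#'   rows; must all be present in the identity matrix.
#' @param cutoff percent identity defining "same species" (default 99).
#' @return logical matrix: `TRUE` where the pair's identity >= cutoff.
#' @export
pair_labels <- function(identity, ids, cutoff = 99) {
  miss <- setdiff(ids, rownames(identity))
  if (length(miss))
    stop("ids missing from identity matrix: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  m <- unclass(identity)[ids, ids] >= cutoff
  diag(m) <- TRUE
  m
}

#' Random-search loop 2: minimize within/between similarity overlap
#'
#' For each draw: preprocess and align the QC-passing spectra, compute the
#' similarity matrix (raw cosine by default; Jaccard-weighted cosine when
#' `use_weighted`), and evaluate [objective_discrimination()] against pairs
#' labelled by 16S identity. Best = lowest overlap, ties broken by higher
#' mean within-class Jaccard, then lower iteration index.
#'
#' @param spectra QC-passing isolate spectra (one per isolate).
#' @param identity an [identity_matrix()] keyed by `isolate_id`.
#' @param ranges a [param_ranges()].
#' @param n_iter number of draws.
#' @param seed integer RNG seed.
#' @param cutoff percent-identity cutoff for within-pairs (default 99).
#' @param use_weighted optimize the weighted rather than raw cosine.
#' @return list `trace`, `best`.
#' @export
run_loop2 <- function(spectra, identity, ranges = param_ranges(),
                      n_iter = 50, seed = 1, cutoff = 99,
                      use_weighted = FALSE) {
  iso <- vapply(spectra, `[[`, "", "isolate_id")
  labels <- pair_labels(identity, iso, cutoff)
  set.seed(seed)
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    p <- sample_params(ranges)
    res <- tryCatch({
      fm <- align_library(spectra, p)
      if (ncol(fm$intensity) == 0) stop("no bins")
      J <- jaccard_matrix(fm)
      S <- if (use_weighted) {
        C <- cosine_matrix(fm)
        weight_cosine(C, J, fit_hyperbolic(J, C))
      } else cosine_matrix(fm)
      ut <- upper.tri(J)
      list(overlap = objective_discrimination(S, labels),
           within_jaccard = mean(J[ut & labels]),
           total_bins = ncol(fm$intensity), failed = FALSE)
    }, error = function(e)
      list(overlap = 0.5, within_jaccard = 0, total_bins = 0L, failed = TRUE))
    rows[[i]] <- cbind(data.frame(iteration = i),
                       as.data.frame(unclass(p)),
                       as.data.frame(res))
  }
  trace <- do.call(rbind, rows)
  o <- order(trace$overlap, -trace$within_jaccard, trace$iteration)
  best <- trace[o[1], ]
  list(trace = trace, best = trace_row_params(best))
}
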