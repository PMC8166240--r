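---
title: "Dereplicating isolate libraries from MALDI-TOF fingerprints: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating isolate libraries from MALDI-TOF fingerprints: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldidrep)
```

## Scope and model

`maldidrep` sorts a library of microbial isolates into MALDI-TOF taxonomic
units (MTUs): clusters of isolates whose linear-mode protein fingerprints
exceed a similarity threshold, playing the role that OTUs play in amplicon
surveys. The pipeline's stages and the quantities they estimate are
described below, together with every place where a genuine design choice
had to be made and why it was resolved the way it was.

The working assumptions are those of linear-mode protein biotyping over the
low-mass window (1,880–20,000 Da): peaks are dominated by abundant
cytosolic proteins (ribosomal proteins above all), peak *positions* are the
reproducible species signal while peak *heights* vary strongly between
spots and instruments, and spectra acquired on different steel targets show
a small systematic, approximately linear mass drift.

## Preprocessing

The chain is fixed: Savitzky–Golay smoothing → top-hat baseline
subtraction → total-ion-current (TIC) normalization → peak detection.

* **Smoothing** is a single-pass Savitzky–Golay filter of window
  `2·half_window + 1` points, polynomial order 3. Order 3 is the common
  default for protein profiles; it transmits cubic trends (hence peak
  shapes wider than the window) unchanged. The vendor pipeline applies 10
  smoothing cycles of a fixed narrow width; here a single pass is used and
  the half-window itself is the tuned free parameter. Edge points are
  fitted with asymmetric windows so polynomial exactness holds up to the
  boundary; negative outputs are clipped to zero.
* **Baseline** is the morphological opening (erosion then dilation, flat
  structuring element of `2·half_window + 1` points) subtracted from the
  signal — the top-hat transform. Opening is idempotent, which the test
  suite asserts. The Rcpp kernel uses a monotonic-deque running extremum
  (O(n)), with window shrinkage at the spectrum edges.
* **TIC normalization** divides intensities by their sum. Cosine similarity
  is scale-invariant, but the *binned* intensity matrix aggregates raw
  intensities across spectra, so a common scale is applied before
  detection. This resolves an open choice (no normalization vs TIC) in
  favor of TIC; `normalize_tic()` is a separate step so callers can omit
  it.
* **Noise** is `1.4826 × MAD` of the intensity about its median — robust to
  the sparse peaks sitting on top of the noise floor. A spectrum whose MAD
  is exactly zero (noise-free synthetic input) yields peaks flagged with
  `snr = Inf` rather than an error.
* **Peak detection** reports grid points that are (a) the maximum within
  `half_window` points on either side and (b) at least `snr ×` noise.
  Equal-intensity ties within a window are broken toward lower m/z, making
  detection fully deterministic. An exhaustive O(n·w) scan oracle verifies
  the kernel over random draws in the tests.

## Alignment and binning

Anchor peaks (SNR ≥ `align_snr`, detected with `align_halfwindow`) are
pooled across spectra and grouped within the relative tolerance; groups
present in ≥90% of spectra become reference masses (the 0.9 cutoff is the
convention of the field's alignment tools and is configurable). Each
spectrum receives a **linear** mass correction `mz' = a·mz + b` fitted by
least squares on its matched references — linear because per-target TOF
drift is multiplicative to first order and because the handful of
reference peaks typical here cannot support a nonparametric warp. Spectra
with fewer than two matches are passed through unwarped and flagged.
Corrections are estimated on the anchor lists and applied to the reporting
peak lists (detected with `peak_halfwindow`/`peak_snr`), which is how all
seven tunable parameters act.

Binning is strict: pooled peaks are recursively split at the largest mass
gap until every bin lies within `tolerance × mean` of its mean *and* no
bin holds two peaks of one spectrum. A same-spectrum conflict at exactly
coincident masses keeps the more intense peak; every drop is counted so
that `sum(presence) + n_dropped` equals the number of input peaks — an
invariant the tests assert exactly. Binning is order-invariant because it
operates on the sorted pool.

## Similarity and the hyperbolic weighting

Over the aligned bins the package computes Jaccard J (presence sets) and
cosine C (intensity vectors). Spectra sharing almost no peaks still show
substantial cosine similarity, driven by peak-height variability in a few
shared dominant masses. The weighting model

$$\hat y(x) = y_0 + \frac{x}{x + 0.2}$$

captures this: $y_0$ is the mean cosine of pairs with J below 0.05
(strictly "J = 0" is rarely populated; with fewer than 10 such pairs the
lowest decile of J is used, with a warning), and the saturation constant
is fixed at 0.2 — it is part of the model definition, not refit. The
**combiner** is the genuinely open choice: the source text says cosines
"were weighted by" the normalized Jaccard without giving the algebra. The
default multiplies the observed cosine by the clamped prediction,
`W = C · clamp(ŷ(J), 0, 1)`, because that is the only reading under which
the weighted axis remains a cosine-scaled similarity in [0, 1]; `min` and
`geometric_mean` combiners are exposed in the configuration for
sensitivity analysis. W is clipped to [0, 1] and its diagonal reset to 1.

## The two random-search loops and QC

Both loops draw the seven parameters independently and uniformly
(integers for half-windows, log-uniform for the relative tolerance, which
spans two orders of magnitude) from configurable ranges. The default
ranges — smoothing 2–25, baseline 10–200, alignment half-window 5–50,
tolerance 2·10⁻⁴–10⁻², SNRs 1–10, peak half-window 5–50 — bracket common
settings for ~1 Da-gridded linear-mode spectra; the archival ranges are
not recoverable from the text, so these are package defaults, not
archival constants.

* **Loop 1** scores each draw by the mean pairwise Jaccard between
  per-target average BTS peak sets (peak positions only, deliberately
  insensitive to height variability). Ties break by shared-peak count,
  then iteration index. A draw whose preprocessing fails (e.g. window
  longer than the spectrum) scores 0 with a flag instead of aborting the
  search.
* **QC** between the loops: a spectrum passes iff the median SNR of its 10
  most intense peaks is ≥15 and it has ≥13 peaks — a pure function of its
  own peak list. Spectra with fewer than 10 peaks use the median over all
  their peaks.
* **Loop 2** scores each draw by the overlap between the similarity
  distributions of "same species" pairs (16S identity ≥99%) and all other
  pairs. The text names no overlap statistic; the package uses the
  balanced misclassification rate minimized over all thresholds,
  `min_t [P(within < t) + P(between ≥ t)]/2` — 0 when separable, 0.5 at
  random, and invariant under monotone transforms of the similarity
  (asserted property). Loop 2 optimizes the **raw** cosine by default
  (whether the original optimization used weighted cosine is unstated; a
  `use_weighted` switch is provided).

The full loop-1 → QC → loop-2 chain is bit-reproducible given the seed,
which the tests assert.

## MTU threshold and clustering

Isolates are clustered by average linkage on `1 − W` and the tree is cut
at `1 − threshold`. The operating threshold can be fixed (default 0.65,
the published operating value) or derived from a four-parameter logistic
fit of percent 16S identity against weighted cosine:
`threshold = round(midpoint, 2) − 0.01`, encoding the published inspection
step (midpoint 0.66 → working threshold 0.65). On synthetic libraries,
whose weighted-cosine scale varies with the draw, the derived threshold is
the appropriate route and is what the acceptance runs use.

Fitting the logistic needs care: identity-vs-similarity data often form
two clumps (within-species ≈ 99.5%, between ≈ 85%) with an empty gap, so
the self-starting fit can fail with a singular gradient and the midpoint
is unidentified along a ridge of equal residual sum of squares inside the
gap. The package first tries the self-starting fit (with a convergence
`scaleOffset` so exact fits do not error); on failure it profiles the
(midpoint, scale) pair on a grid — the asymptote pair is linear given the
other two and is solved exactly, with asymptotes bounded to [0, 100]
because identities are percentages — and returns the **center** of the
RSS-tie ridge, polishing with a bounded Newton fit only when that
genuinely improves the fit. This makes the derived threshold land in the
middle of the between/within gap rather than at an arbitrary edge.

Bootstrap support resamples feature-matrix **columns** (bins) with
replacement, recomputes W and the dendrogram, and reports per-node BP
values; with `au = TRUE` a ten-scale multiscale bootstrap (0.5–1.4 × the
bin count) and the probit regression `z(r) = v√r + c/√r` give
`AU = 1 − Φ(v − c)`. AU is optional because the multiscale pass multiplies
the bootstrap cost by ten.

## Diversity estimation

From the MTU abundance vector (n isolates, s_obs MTUs, f1 singletons, f2
doubletons) the package computes exact hypergeometric rarefaction
(asserted equal to brute-force subsample enumeration for n ≤ 15), Chao1
extrapolation `S(n+m*) = s_obs + f̂0·[1 − (1 − f1/(n·f̂0 + f1))^{m*}]` with
`f̂0 = ((n−1)/n)·f1²/(2f2)` (the f2 = 0 variant when needed), and the
abundance-based coverage estimator. Only richness (Hill order q = 0) is
implemented — it is the quantity the dereplication workflow reports.
Confidence intervals come from a seeded multinomial bootstrap of the
observed relative abundances (200 replicates by default); this is simpler
than the full incidence-adjusted bootstrap of dedicated
rarefaction packages and is documented as such. Extrapolation is capped at
2n by default, matching the doubling convention of the workflow.

## Classification

The default classifier is nearest centroid on cosine distance: rows are
scaled to unit norm, class centroids are means of unit rows, prediction
maximizes cosine to centroid. It is deterministic, tuning-free and
transparent — appropriate when the reported headline is "100% correct",
which any sufficiently flexible learner can reach on replicated MTUs. A
small CART-style tree (Gini splits on single bins, grown to purity) is the
alternative. Training requires ≥2 members per class, so singleton MTUs
must be discarded first (the error says so); leave-one-out folds relax
this internally, since removing one member of a duplicated class is the
point of the scheme. Both resubstitution and leave-one-out reports are
produced, because the published perfect score is consistent with either.

## The synthetic world

The generator emulates, with full ground truth: species-level peak
templates (30 peaks, uniform masses, log-normal amplitudes with ~20-fold
95% dynamic range); strain variation that retains 90% of the template —
always including the top third by intensity, because a species' dominant
peaks are its conserved ones — and replaces the rest with minor private
peaks at half amplitude; a conserved set (10% of the template) of dominant
masses shared by *all* species with correlated intensities, standing in
for the major ribosomal proteins; Gaussian peak shapes (σ = 3 Da) on a
1 Da grid over 1,880–20,000 Da; an exponentially decaying baseline and
unit Gaussian noise (median peak SNR ≈ 50); multiplicative per-target mass
drift (5·10⁻⁴ between adjacent targets); replicate BTS spectra from one
fixed 21-peak stratified-mass template; a matched synthetic 16S identity
matrix (99.5 ± 0.3% within species, 85 ± 3% between); and optional planted
QC failures (amplitudes rescaled to median 1.5× noise, or templates
truncated to 6 peaks).

What it does **not** emulate: detector saturation, isotope envelopes,
correlated (pink) noise, mass-dependent resolution, chimeric colonies, or
any taxonomic structure beyond a two-level within/between dichotomy in the
identity matrix. A green end-to-end test therefore establishes that the
pipeline recovers a planted species partition under realistic drift,
noise and strain variation — not that it reproduces any particular real
library's MTU count.

## Degenerate inputs and tie-breaks (summary)

All-zero spectra fail TIC normalization with a specific error; zero noise
gives `snr = Inf` flagged peaks; empty peak lists fail QC rather than
erroring; empty-union Jaccard pairs are 0 and flagged; an absent
between-class or within-class pair set is an error naming the class;
window-maximum ties go to lower m/z; loop ties go to better secondary
objective then lower iteration; same-spectrum bin conflicts keep the
higher intensity; MTU ids are assigned in order of first appearance.

## Known limitations

* Native Bruker fid/acqu files are not parsed; export to mzML or
  two-column text first. The mzML reader is minimal (first spectrum,
  64/32-bit floats, optional zlib).
* The linear warp cannot correct nonlinear mass error; with fewer than two
  reference peaks a spectrum is left unwarped.
* The bootstrap for diversity CIs ignores unseen-species probability mass.
* The two-clump identity structure of the synthetic world makes the
  logistic midpoint interval-identified; the ridge-center rule is a
  convention, and on real, continuously spread identity data the ordinary
  fit applies.
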