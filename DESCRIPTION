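Package: maldidrep
Title: Dereplication of Microbial Isolate Libraries from MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R:
    person("Maize", "Culturomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocesses linear-mode MALDI-TOF profile spectra (Savitzky-Golay
    smoothing, top-hat baseline removal, TIC normalization, SNR-gated peak
    detection), aligns and bins peaks across spectra, tunes the seven
    preprocessing/alignment parameters with two seeded random-search loops
    separated by an SNR/peak-count quality-control filter, computes
    Jaccard-weighted cosine similarities, clusters isolates into MALDI-TOF
    taxonomic units (MTUs) at a similarity threshold derived from a sigmoidal
    fit of 16S identity against weighted cosine similarity, estimates library
    diversity by rarefaction/extrapolation with sample coverage, and trains a
    nearest-centroid MTU classifier. Ships a synthetic-spectrum generator with
    known ground truth so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
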