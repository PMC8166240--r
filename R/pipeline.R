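#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with the
#' operating constants used throughout: QC gate of median top-10 SNR 15 and
#' 13 peaks, MTU threshold 0.65, average linkage, multiply combiner.
#' Values can be overridden by a (possibly partial) list or YAML file.
#'
#' @param overrides named list (or path of a YAML file) of overrides; nested
#'   lists are merged recursively.
#' @return configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    paths = list(spectra_dir = NULL, metadata = NULL, identity = NULL,
                 out_dir = "maldidrep_run"),
    seed = 1,
    mass_range = c(1880, 20000),
    ranges = list(),                       # param_ranges() overrides
    loop1 = list(n_iter = 50),
    loop2 = list(n_iter = 50, cutoff = 99, use_weighted = FALSE),
    qc = list(snr_threshold = 15, top_k = 10, min_peaks = 13),
    similarity = list(combiner = "multiply", epsilon = 0.05),
    cluster = list(threshold = 0.65, from_sigmoid = FALSE,
                   linkage = "average", n_boot = 0),
    diversity = list(n_boot = 200),
    classify = list(method = "centroid")
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Run the full dereplication pipeline
#'
#' Executes the stage chain: random-search loop 1 on the BTS reference
#' spectra -> quality control of isolate spectra with the loop-1 parameters
#' -> random-search loop 2 on the QC-passing isolates against the 16S
#' identity matrix -> alignment/binning with the loop-2 parameters ->
#' Jaccard/cosine/weighted similarity -> MTU clustering -> rarefaction and
#' coverage -> MTU classifier training and evaluation. Every intermediate
#' table is written under `config$paths$out_dir` along with a JSON manifest
#' recording the seed, package version and configuration, so the run is
#' reproducible from the manifest alone.
#'
#' @param spectra list of [maldi_spectrum()] (isolates + BTS references);
#'   alternatively `NULL` to read from `config$paths`.
#' @param identity an [identity_matrix()] keyed by isolate id (or `NULL` to
#'   read from `config$paths$identity`).
#' @param config list from [default_config()].
#' @param params optional [param_set()]: skip both optimization loops and
#'   use these parameters directly.
#' @param write write artifact CSVs and manifest (default `TRUE` when
#'   `out_dir` is set).
#' @return list of class `pipeline_result` with elements `best1`, `best2`,
#'   `qc`, `similarity`, `mtus`, `diversity`, `classifier`, `manifest`.
#' @export
run_pipeline <- function(spectra = NULL, identity = NULL,
                         config = default_config(), params = NULL,
                         write = !is.null(config$paths$out_dir)) {
  if (is.null(spectra)) {
    paths <- list.files(config$paths$spectra_dir, full.names = TRUE,
                        pattern = "\\.(csv|tsv|txt|mzml|mzML)$")
    paths <- paths[!grepl("metadata|identity|truth", basename(paths))]
    spectra <- read_spectra(paths, config$paths$metadata,
                            mass_range = config$mass_range)
  }
  if (is.null(identity) && !is.null(config$paths$identity))
    identity <- read_identity_matrix(config$paths$identity)
  out_dir <- config$paths$out_dir
  if (write) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, name) {
    if (write) write_table(obj, file.path(out_dir, name))
  }
  ranges <- do.call(param_ranges, config$ranges)
  bts <- Filter(function(s) s$group == "bts_reference", spectra)
  isolates <- Filter(function(s) s$group == "isolate", spectra)
  isolates <- merge_isolate_replicates(isolates)

  # loops 1-2 (or supplied parameters)
  if (is.null(params)) {
    l1 <- run_loop1(spectra, ranges, n_iter = config$loop1$n_iter,
                    seed = config$seed)
    emit(l1$trace, "loop1_trace.csv")
    best1 <- l1$best
  } else {
    l1 <- NULL; best1 <- params
  }

  pls <- lapply(isolates, preprocess_spectrum, params = best1)
  qc <- qc_filter(pls, snr_threshold = config$qc$snr_threshold,
                  top_k = config$qc$top_k, min_peaks = config$qc$min_peaks)
  emit(as.data.frame(qc), "qc_report.csv")
  passing <- isolates[qc$passed]
  if (length(passing) < 3)
    stop("stage qc: fewer than 3 spectra passed", call. = FALSE)

  if (is.null(params) && !is.null(identity)) {
    l2 <- run_loop2(passing, identity, ranges,
                    n_iter = config$loop2$n_iter, seed = config$seed + 1,
                    cutoff = config$loop2$cutoff,
                    use_weighted = config$loop2$use_weighted)
    emit(l2$trace, "loop2_trace.csv")
    best2 <- l2$best
  } else {
    l2 <- NULL; best2 <- best1
  }

  # similarity on passing isolates (+ per-target BTS averages, if any)
  extra <- if (length(bts)) {
    by_t <- split(bts, vapply(bts, `[[`, "", "target_id"))
    lapply(names(by_t), function(tn)
      average_replicates(by_t[[tn]], spectrum_id = paste0("BTS_", tn)))
  } else list()
  fm <- align_library(c(passing, extra), best2)
  emit(fm, "feature_matrix.csv")
  sim <- similarity_bundle(fm, epsilon = config$similarity$epsilon,
                           combiner = config$similarity$combiner)
  emit(sim$weighted, "weighted_similarity.csv")

  # threshold: fixed, or derived from the 16S-vs-weighted-cosine sigmoid
  threshold <- config$cluster$threshold
  sigmoid <- NULL
  if (isTRUE(config$cluster$from_sigmoid) && !is.null(identity)) {
    iso_ids <- vapply(passing, `[[`, "", "isolate_id")
    keep <- match(iso_ids, fm$spectrum_ids)
    ut <- upper.tri(diag(length(iso_ids)))
    sigmoid <- fit_sigmoid(sim$weighted[keep, keep][ut],
                           unclass(identity)[iso_ids, iso_ids][ut])
    threshold <- threshold_from_sigmoid(sigmoid)
  }
  iso_rows <- match(vapply(passing, `[[`, "", "spectrum_id"), fm$spectrum_ids)
  W_iso <- sim$weighted[iso_rows, iso_rows]
  mtus <- cluster_mtus(W_iso, threshold = threshold,
                       linkage = config$cluster$linkage)
  emit(mtus$table, "mtu_table.csv")
  support <- NULL
  if (config$cluster$n_boot >= 100) {
    support <- bootstrap_support(fm, n_boot = config$cluster$n_boot,
                                 seed = config$seed + 2,
                                 combiner = config$similarity$combiner,
                                 linkage = config$cluster$linkage)
    if (write) write_newick(support, file.path(out_dir, "dendrogram.nwk"))
  }

  av <- abundance_from_mtus(mtus)
  div <- rarefy_extrapolate(av, n_boot = config$diversity$n_boot,
                            seed = config$seed + 3)
  emit(as.data.frame(div), "diversity_curve.csv")

  # classifier on replicated MTUs (+ BTS rows as their own class)
  classifier <- tryCatch({
    lab <- mtus$table$mtu_id[match(fm$spectrum_ids, mtus$table$spectrum_id)]
    lab <- ifelse(is.na(lab), "BTS", paste0("MTU", lab))
    keep <- lab %in% names(which(table(lab) >= 2))
    fmr <- feature_matrix(fm$bin_mz, fm$spectrum_ids[keep],
                          fm$intensity[keep, , drop = FALSE])
    mdl <- train_classifier(fmr, lab[keep], method = config$classify$method)
    list(model = mdl,
         resubstitution = evaluate_classifier(mdl, fmr, lab[keep],
                                              "resubstitution"),
         loo = evaluate_classifier(mdl, fmr, lab[keep], "loo"))
  }, error = function(e) {
    warning("classifier stage skipped: ", conditionMessage(e))
    NULL
  })

  manifest <- list(package = "maldidrep",
                   version = as.character(utils::packageVersion("maldidrep")),
                   seed = config$seed, threshold = threshold,
                   n_spectra = length(spectra),
                   n_passing = length(passing),
                   n_mtus = mtus$n_mtus, config = config)
  if (write)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(best1 = best1, best2 = best2, loop1 = l1, loop2 = l2,
                 qc = qc, feature_matrix = fm, similarity = sim,
                 sigmoid = sigmoid, mtus = mtus, support = support,
                 diversity = div, classifier = classifier,
                 manifest = manifest),
            class = "pipeline_result")
}

# one spectrum per isolate: average replicate spots acquired for the same
# isolate before entering the loops
merge_isolate_replicates <- function(isolates) {
  ids <- vapply(isolates, `[[`, "", "isolate_id")
  if (!anyDuplicated(ids)) return(isolates)
  lapply(split(isolates, ids), function(group) {
    if (length(group) == 1) group[[1]]
    else average_replicates(group, spectrum_id = group[[1]]$isolate_id)
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$mtus)
  cat(sprintf("  coverage %.3f, Chao1 %.1f\n",
              coverage(abundance_from_mtus(x$mtus)),
              attr(x$diversity, "chao1")))
  if (!is.null(x$classifier))
    cat(sprintf("  classifier: resub accuracy %.3f (kappa %.3f), LOO accuracy %.3f\n",
                x$classifier$resubstitution$accuracy,
                x$classifier$resubstitution$kappa,
                x$classifier$loo$accuracy))
  invisible(x)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic input set), `run-all` (full
#' pipeline from a config file or path flags), `qc`, `cluster`,
#' `diversity`, `classify` (stage re-runs from the documented CSV
#' artifacts). Invoke via the installed `exec/maldidrep` script:
#' `maldidrep run-all --config cfg.yaml`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, invisibly.
#' @export
maldidrep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: maldidrep <simulate|run-all|qc|cluster|diversity|classify> [options]",
    "  simulate  --out DIR [--seed S] [--species N] [--strains K]",
    "            [--degrade-snr N] [--degrade-peaks N]",
    "  run-all   --config cfg.yaml | --spectra-dir D --metadata M",
    "            [--identity I] --out DIR [--seed S] [--iters N]",
    "  qc        --peaklists peaks.csv [--snr 15 --top 10 --min-peaks 13]",
    "  cluster   --similarity W.csv [--threshold 0.65] [--linkage average]",
    "            --out mtus.csv",
    "  diversity --mtus mtus.csv --out curve.csv [--seed S]",
    "  classify  --features fm.csv --mtus mtus.csv --out report.json",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_flags(args[-1])
  get <- function(name, default = NULL) opt[[name]] %||% default
  num <- function(name, default = NULL) {
    v <- get(name); if (is.null(v)) default else as.numeric(v)
  }
  switch(cmd,
    "simulate" = {
      cfg <- synth_config(n_species = num("species", 20),
                          strains_per_species = num("strains", 3),
                          seed = num("seed", 1))
      lib <- generate_library(cfg,
                              degrade_snr = num("degrade-snr", 0),
                              degrade_peaks = num("degrade-peaks", 0))
      bts <- generate_bts(cfg)
      write_synth_library(lib, get("out", "synthetic_library"), bts = bts)
      message("wrote synthetic library to ", get("out", "synthetic_library"))
    },
    "run-all" = {
      config <- default_config(get("config"))
      if (!is.null(get("spectra-dir")))
        config$paths$spectra_dir <- get("spectra-dir")
      if (!is.null(get("metadata"))) config$paths$metadata <- get("metadata")
      if (!is.null(get("identity"))) config$paths$identity <- get("identity")
      if (!is.null(get("out"))) config$paths$out_dir <- get("out")
      if (!is.null(get("seed"))) config$seed <- num("seed")
      if (!is.null(get("iters"))) {
        config$loop1$n_iter <- num("iters")
        config$loop2$n_iter <- num("iters")
      }
      res <- run_pipeline(config = config)
      print(res)
    },
    "qc" = {
      df <- read.csv(get("peaklists"))
      pls <- lapply(split(df, df$spectrum_id), function(d)
        peaklist(d$mz, d$intensity, d$snr, spectrum_id = d$spectrum_id[1]))
      rep <- qc_filter(pls, snr_threshold = num("snr", 15),
                       top_k = num("top", 10),
                       min_peaks = num("min-peaks", 13))
      write_table(as.data.frame(rep), get("out", "qc_report.csv"))
    },
    "cluster" = {
      W <- as.matrix(read.csv(get("similarity"), row.names = 1,
                              check.names = FALSE))
      res <- cluster_mtus(W, threshold = num("threshold", 0.65),
                          linkage = get("linkage", "average"))
      write_table(res$table, get("out", "mtus.csv"))
      print(res)
    },
    "diversity" = {
      tab <- read.csv(get("mtus"))
      av <- abundance_from_mtus(tab)
      div <- rarefy_extrapolate(av, seed = num("seed", 1))
      write_table(as.data.frame(div), get("out", "diversity_curve.csv"))
    },
    "classify" = {
      fm <- read_feature_matrix(get("features"))
      tab <- read.csv(get("mtus"))
      lab <- paste0("MTU", tab$mtu_id[match(fm$spectrum_ids, tab$spectrum_id)])
      keep <- lab %in% names(which(table(lab) >= 2)) & !is.na(lab)
      fmr <- feature_matrix(fm$bin_mz, fm$spectrum_ids[keep],
                            fm$intensity[keep, , drop = FALSE])
      mdl <- train_classifier(fmr, lab[keep])
      rep <- evaluate_classifier(mdl, fmr, lab[keep], "loo")
      jsonlite::write_json(
        list(confusion = rep$confusion, accuracy = rep$accuracy,
             kappa = rep$kappa, scheme = rep$scheme),
        get("out", "classifier_report.json"), auto_unbox = TRUE, digits = NA)
      print(rep)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}
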