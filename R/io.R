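#' Read profile spectra from delimited text or mzML files
#'
#' Each path is either a two-column delimited file (m/z, intensity; comma or
#' tab, auto-detected, optional header) or an mzML file holding one spectrum.
#' A metadata table links files to isolates, replicate-spot groups and target
#' plates. One spectrum per file; replicate spots are separate files tied
#' together by `isolate_id`.
#'
#' @param paths character vector of spectrum file paths.
#' @param meta either the path of a metadata CSV or a data.frame with columns
#'   `spectrum_id,isolate_id,group,target_id` (optional `species_label`,
#'   `niche`, `variety`); `spectrum_id` must match `basename(path)` stripped
#'   of its extension. `NULL` derives ids from filenames with defaults.
#' @param mass_range declared acquisition range passed to [maldi_spectrum()].
#' @return list of [maldi_spectrum()] objects.
#' @export
read_spectra <- function(paths, meta = NULL, mass_range = c(1880, 20000)) {
  meta <- read_metadata(meta)
  lapply(paths, function(p) {
    if (!file.exists(p)) stop("spectrum file not found: ", p, call. = FALSE)
    xy <- if (grepl("\\.mzml$", p, ignore.case = TRUE)) read_mzml_xy(p)
          else read_xy_table(p)
    sid <- sub("\\.[^.]*$", "", basename(p))
    m <- meta[match(sid, meta$spectrum_id), , drop = FALSE]
    if (!is.null(meta) && (nrow(m) == 0 || is.na(m$spectrum_id[1])))
      stop("no metadata row for spectrum '", sid, "'", call. = FALSE)
    maldi_spectrum(xy$mz, xy$intensity, spectrum_id = sid,
                   isolate_id = if (is.null(meta)) sid else m$isolate_id[1],
                   group = if (is.null(meta)) "isolate" else m$group[1],
                   target_id = if (is.null(meta)) "T1" else m$target_id[1],
                   mass_range = mass_range)
  })
}

read_metadata <- function(meta) {
  if (is.null(meta)) return(NULL)
  if (is.character(meta)) {
    if (!file.exists(meta)) stop("metadata file not found: ", meta, call. = FALSE)
    meta <- read.csv(meta, stringsAsFactors = FALSE)
  }
  req <- c("spectrum_id", "isolate_id", "group", "target_id")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$spectrum_id))
    stop("duplicate spectrum_id in metadata", call. = FALSE)
  meta
}

# Two-column m/z,intensity table; delimiter sniffed among comma/tab.
read_xy_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- {
    f1 <- strsplit(first, sep, fixed = TRUE)[[1]][1]
    is.na(suppressWarnings(as.numeric(f1)))
  }
  df <- tryCatch(
    read.table(path, sep = sep, header = has_header,
               colClasses = "numeric", col.names = c("mz", "intensity")),
    error = function(e) {
      # locate the first bad row for the error message
      raw <- read.table(path, sep = sep, header = has_header,
                        colClasses = "character")
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[1]]))) |
                   is.na(suppressWarnings(as.numeric(raw[[2]]))))[1]
      stop("non-numeric row ", bad + has_header, " in ", path, call. = FALSE)
    })
  if (ncol(df) < 2) stop("expected two columns in ", path, call. = FALSE)
  list(mz = df[[1]], intensity = df[[2]])
}

# Minimal mzML reader: first spectrum's m/z and intensity binary arrays.
# Supports 32/64-bit floats, optional zlib compression, base64 encoding.
read_mzml_xy <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spec <- xml2::xml_find_first(doc, ".//spectrum")
  if (inherits(spec, "xml_missing")) stop("no <spectrum> in ", path, call. = FALSE)
  arrays <- xml2::xml_find_all(spec, ".//binaryDataArray")
  out <- list()
  for (a in arrays) {
    accs <- xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "accession")
    is64 <- "MS:1000523" %in% accs
    is32 <- "MS:1000521" %in% accs
    zlib <- "MS:1000574" %in% accs
    kind <- if ("MS:1000514" %in% accs) "mz"
            else if ("MS:1000515" %in% accs) "intensity" else next
    b64 <- xml2::xml_text(xml2::xml_find_first(a, ".//binary"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
    if (zlib) raw <- memDecompress(raw, type = "gzip")
    size <- if (is64 || !is32) 8L else 4L
    out[[kind]] <- readBin(raw, "double", n = length(raw) %/% size,
                           size = size, endian = "little")
  }
  if (is.null(out$mz) || is.null(out$intensity))
    stop("mzML file lacks m/z or intensity array: ", path, call. = FALSE)
  out
}

#' Read a pairwise 16S percent-identity matrix
#'
#' Square CSV with sequence ids as header row and first column. Small
#' asymmetries (at most 0.5 percentage points) are symmetrized by averaging;
#' larger ones are errors, as is a diagonal that is not 100 (within 0.01).
#'
#' @param path CSV path.
#' @return an `identity_matrix`: a numeric matrix with a `sequence_ids`
#'   dimnames, values in percent.
#' @export
read_identity_matrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  identity_matrix(m)
}

#' Validate/construct a 16S identity matrix
#' @param m square numeric matrix (percent identity) with dimnames.
#' @return validated matrix of class `identity_matrix`.
#' @export
identity_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("identity matrix must be square", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("identity matrix row/column ids differ", call. = FALSE)
  storage.mode(m) <- "double"
  asym <- abs(m - t(m))
  if (any(asym > 0.5))
    stop("identity matrix asymmetry exceeds 0.5 percentage points", call. = FALSE)
  m <- (m + t(m)) / 2
  if (any(abs(diag(m) - 100) > 0.01))
    stop("identity matrix diagonal must be 100", call. = FALSE)
  diag(m) <- 100
  if (any(m < 0 | m > 100))
    stop("identities must lie in [0, 100]", call. = FALSE)
  structure(m, class = c("identity_matrix", "matrix", "array"))
}

#' Write package tables as delimited text
#'
#' A single dispatcher for the package's tabular artifacts (feature matrices,
#' similarity matrices, MTU tables, peak lists, optimization traces, QC
#' reports). Output is CSV with a header and deterministic column order, and
#' is re-readable by the matching `read_*` function.
#'
#' @param object the object to serialize.
#' @param path output file path.
#' @export
write_table <- function(object, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(object, path) {
  write.csv(object, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.matrix <- function(object, path) {
  df <- as.data.frame(object)
  df[] <- lapply(df, fmt_full)
  write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

# full-precision numeric formatting so write/read round-trips are exact
fmt_full <- function(x) if (is.double(x)) sprintf("%.17g", x) else x

#' @export
write_table.feature_matrix <- function(object, path) {
  df <- as.data.frame(object$intensity)
  names(df) <- sprintf("%.6f", object$bin_mz)
  df <- cbind(spectrum_id = object$spectrum_ids, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.peaklist <- function(object, path) {
  df <- data.frame(spectrum_id = attr(object, "spectrum_id"),
                   mz = object$mz, intensity = object$intensity,
                   snr = object$snr)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_table()]
#' @param path CSV path.
#' @return a `feature_matrix` object.
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ints <- as.matrix(df[, -1, drop = FALSE])
  feature_matrix(bin_mz = as.numeric(colnames(ints)),
                 spectrum_ids = df[[1]], intensity = unname(ints))
}

#' Write a spectrum as a two-column CSV
#' @param spectrum a [maldi_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  writeLines(c("mz,intensity",
               sprintf("%.17g,%.17g", spectrum$mz, spectrum$intensity)),
             path)
  invisible(path)
}
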