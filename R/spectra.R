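#' @title Centroid spectra
#' @description A spectrum is the centroided MS1 peak list of one well:
#'   a `sample_id` plus a two-column peak table (m/z in Da, intensity),
#'   kept sorted ascending by m/z. Collections of spectra are plain lists.
#' @name spectra
NULL

#' Construct a spectrum
#'
#' @param sample_id Well identifier.
#' @param mz Numeric vector of peak m/z values (Da, > 0).
#' @param intensity Numeric vector of peak intensities (>= 0), same length.
#' @return An object of class `spectrum`: a list with `sample_id` and a
#'   `peaks` data frame sorted ascending by m/z (duplicate m/z allowed).
#' @examples
#' spectrum("well_A1", mz = c(760.5851, 703.5749), intensity = c(100, 40))
#' @export
spectrum <- function(sample_id, mz = numeric(), intensity = numeric()) {
  if (length(mz) != length(intensity)) {
    stop_sclipid("mz and intensity must have equal length",
                 class = "sclipid_validation_error")
  }
  if (length(mz) > 0L && (any(!is.finite(mz)) || any(mz <= 0))) {
    stop_sclipid("spectrum '%s': all m/z must be finite and > 0", sample_id,
                 class = "sclipid_validation_error")
  }
  if (length(intensity) > 0L && (any(!is.finite(intensity)) || any(intensity < 0))) {
    stop_sclipid("spectrum '%s': all intensities must be finite and >= 0",
                 sample_id, class = "sclipid_validation_error")
  }
  ord <- order(mz)
  structure(list(sample_id = as.character(sample_id),
                 peaks = data.frame(mz = as.numeric(mz[ord]),
                                    intensity = as.numeric(intensity[ord]))),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d peaks", x$sample_id, nrow(x$peaks)))
  if (nrow(x$peaks) > 0L) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$peaks$mz), max(x$peaks$mz)))
  }
  cat(">\n")
  invisible(x)
}

#' Read spectra from peak-list CSV or mzML
#'
#' Two layouts are accepted for `format = "peaklist_csv"`:
#' \itemize{
#'   \item a directory: every `*.csv` inside is one spectrum with columns
#'     `mz,intensity`; the sample id is the file name without extension;
#'   \item a single file: either two columns `mz,intensity` (one spectrum,
#'     sample id = file name without extension) or a long table with columns
#'     `sample_id,mz,intensity` holding many spectra.
#' }
#' For `format = "mzml"` each spectrum in the file is one well; the sample
#' id is taken from the scan's `spectrumId` (the text after the last `=` is
#' stripped of instrument framing), falling back to
#' `<file>_scan<N>`. Reading mzML requires the `mzR` package.
#'
#' @param path File or directory path.
#' @param format `"peaklist_csv"` (default) or `"mzml"`.
#' @return A list of [spectrum()] objects, peaks sorted ascending by m/z.
#' @export
read_spectra <- function(path, format = c("peaklist_csv", "mzml")) {
  format <- match.arg(format)
  if (format == "mzml") {
    return(.read_spectra_mzml(path))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) {
      stop_sclipid("directory '%s' contains no .csv peak lists", path,
                   class = "sclipid_parse_error")
    }
    return(unlist(lapply(files, .read_peaklist_file), recursive = FALSE))
  }
  if (!file.exists(path)) {
    stop_sclipid("spectra path '%s' does not exist", path,
                 class = "sclipid_parse_error")
  }
  .read_peaklist_file(path)
}

.read_peaklist_file <- function(file) {
  df <- tryCatch(utils::read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop_sclipid("cannot parse peak list '%s': %s", file,
                                conditionMessage(e),
                                class = "sclipid_parse_error")
                 })
  id_from_file <- sub("\\.csv$", "", basename(file))
  if (all(c("sample_id", "mz", "intensity") %in% names(df))) {
    ids <- unique(df$sample_id)
    return(lapply(ids, function(id) {
      sub <- df[df$sample_id == id, , drop = FALSE]
      .peaklist_to_spectrum(sub, id, file)
    }))
  }
  df <- assert_columns(df, c("mz", "intensity"), sprintf("'%s'", file))
  list(.peaklist_to_spectrum(df, id_from_file, file))
}

.peaklist_to_spectrum <- function(df, id, file) {
  mz <- suppressWarnings(as.numeric(df$mz))
  it <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad) > 0L) {
    stop_sclipid("'%s': non-numeric peak record at data row %d (sample '%s')",
                 file, bad[1L], id, class = "sclipid_parse_error")
  }
  spectrum(id, mz, it)
}

.read_spectra_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_sclipid("reading mzML requires the 'mzR' package")
  }
  if (!file.exists(path)) {
    stop_sclipid("mzML file '%s' does not exist", path,
                 class = "sclipid_parse_error")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  base <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  out <- lapply(seq_len(nrow(hdr)), function(i) {
    pk <- mzR::peaks(handle, i)
    sid <- hdr$spectrumId[i]
    id <- if (is.character(sid) && nzchar(sid) && grepl("=", sid)) {
      sub("^.*=", "", sid)
    } else {
      as.character(i)
    }
    if (grepl("^[0-9]+$", id)) id <- sprintf("%s_scan%s", base, id)
    spectrum(id, pk[, 1L], pk[, 2L])
  })
  .apply_mzml_ids(out, path)
}

#' Write spectra to peak-list CSVs or a single mzML file
#'
#' With `format = "peaklist_csv"`, `path` is a directory and each spectrum
#' is written as `<sample_id>.csv` with columns `mz,intensity`. With
#' `format = "mzml"`, `path` is a single `.mzML` file holding one MS1
#' centroid scan per spectrum (requires `mzR`); sample ids are stored in an
#' index CSV `<path>.ids.csv` alongside, because mzML scan identifiers are
#' numeric.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output directory (CSV) or file (mzML).
#' @param format `"peaklist_csv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("peaklist_csv", "mzml")) {
  format <- match.arg(format)
  stopifnot(is.list(spectra))
  if (format == "peaklist_csv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (sp in spectra) {
      utils::write.csv(sp$peaks, file.path(path, paste0(sp$sample_id, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(path))
  }
  .write_spectra_mzml(spectra, path)
}

.write_spectra_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_sclipid("writing mzML requires the 'mzR' package")
  }
  n <- length(spectra)
  pks <- lapply(spectra, function(sp) {
    m <- as.matrix(sp$peaks)
    colnames(m) <- c("mz", "intensity")
    m
  })
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(pks, nrow, 0L),
    totIonCurrent = vapply(pks, function(m) sum(m[, 2L]), 0),
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(pks, function(m) if (nrow(m)) m[which.max(m[, 2L]), 1L] else 0, 0),
    basePeakIntensity = vapply(pks, function(m) if (nrow(m)) max(m[, 2L]) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(m) if (nrow(m)) min(m[, 1L]) else 0, 0),
    highMZ = vapply(pks, function(m) if (nrow(m)) max(m[, 1L]) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, file = path, header = hdr)
  ids <- vapply(spectra, `[[`, "", "sample_id")
  utils::write.csv(data.frame(scan = seq_len(n), sample_id = ids),
                   paste0(path, ".ids.csv"), row.names = FALSE)
  invisible(path)
}

#' Read back sample ids for an mzML written by [write_spectra()]
#' @noRd
.apply_mzml_ids <- function(spectra, path) {
  idfile <- paste0(path, ".ids.csv")
  if (!file.exists(idfile)) return(spectra)
  ids <- utils::read.csv(idfile, stringsAsFactors = FALSE)
  for (i in seq_along(spectra)) {
    row <- ids[ids$scan == i, , drop = FALSE]
    if (nrow(row) == 1L) spectra[[i]]$sample_id <- row$sample_id
  }
  spectra
}
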