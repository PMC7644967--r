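#' @title Abundance matrices
#' @description Samples x lipids intensity tables. Missing values (`NA`)
#'   mean "below the lower limit of detection / not detected" and are a
#'   distinct state from a measured zero; they are never silently imputed.
#'   The `normalized` flag records whether each row has been divided by its
#'   total detected signal.
#' @name abundance-matrix
NULL

#' Construct an abundance matrix
#'
#' @param values Numeric matrix, rows = samples (rownames = sample ids),
#'   columns = lipids (colnames = lipid names). `NA` marks a lipid not
#'   detected in a sample.
#' @param normalized Logical flag; if `TRUE`, every row's non-missing values
#'   must sum to 1 within 1e-9.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_sclipid("'values' must be a numeric matrix",
                 class = "sclipid_validation_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_sclipid("abundance matrix needs sample rownames and lipid colnames",
                 class = "sclipid_validation_error")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop_sclipid("abundance matrix has duplicated sample or lipid names",
                 class = "sclipid_validation_error")
  }
  if (any(values[!is.na(values)] < 0)) {
    stop_sclipid("abundance values must be non-negative",
                 class = "sclipid_validation_error")
  }
  if (isTRUE(normalized)) {
    sums <- rowSums(values, na.rm = TRUE)
    if (any(abs(sums - 1) > 1e-9)) {
      stop_sclipid("normalized = TRUE but row sums deviate from 1 (max |sum-1| = %.3g)",
                   max(abs(sums - 1)), class = "sclipid_validation_error")
    }
  }
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix: %d samples x %d lipids, %s, %.1f%% missing>\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw",
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by sample ids and/or lipid names
#'
#' @param x An `abundance_matrix`.
#' @param samples Character vector of sample ids to keep (default all).
#' @param lipids Character vector of lipid names to keep (default all).
#' @return An `abundance_matrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(x, samples = NULL, lipids = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing) > 0L) {
      stop_sclipid("sample(s) not in matrix: %s",
                   paste(utils::head(missing, 5L), collapse = ", "))
    }
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(lipids)) {
    missing <- setdiff(lipids, colnames(v))
    if (length(missing) > 0L) {
      stop_sclipid("lipid(s) not in matrix: %s",
                   paste(utils::head(missing, 5L), collapse = ", "))
    }
    v <- v[, lipids, drop = FALSE]
  }
  # subsetting can break the unit-sum property, so the flag is re-derived
  normalized <- x$normalized &&
    all(abs(rowSums(v, na.rm = TRUE) - 1) <= 1e-9)
  abundance_matrix(v, normalized = normalized)
}

#' Write / read an abundance matrix as CSV
#'
#' The first line is a comment header `#normalized=TRUE|FALSE`; then a CSV
#' with a `sample_id` column followed by one column per lipid. Missing cells
#' are written as empty fields and read back as `NA` (`"NA"` is also
#' accepted). The round trip is lossless, including the flag; values are
#' written with full double precision.
#'
#' @param matrix An `abundance_matrix`.
#' @param path CSV path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` an
#'   `abundance_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("#normalized=%s", matrix$normalized), con)
  df <- data.frame(sample_id = rownames(matrix$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- matrix$values
  for (j in seq_len(ncol(vals))) {
    df[[colnames(vals)[j]]] <- sprintf("%.17g", vals[, j])
    df[[colnames(vals)[j]]][is.na(vals[, j])] <- ""
  }
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_sclipid("matrix file '%s' does not exist", path,
                 class = "sclipid_parse_error")
  }
  first <- readLines(path, n = 1L)
  normalized <- FALSE
  skip <- 0L
  if (startsWith(first, "#normalized=")) {
    normalized <- identical(toupper(sub("#normalized=", "", first)), "TRUE")
    skip <- 1L
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, skip = skip,
                        na.strings = c("", "NA"), check.names = FALSE)
  df <- assert_columns(df, "sample_id", sprintf("'%s'", path))
  ids <- as.character(df$sample_id)
  v <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  abundance_matrix(v, normalized = normalized)
}
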