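#' @title Sample metadata tables
#' @description One row per well: `sample_id`, `sample_type` (one of
#'   `single_cell`, `blank`, `qc_pool`, `curve_standard`), `plate`, `well`,
#'   `injection_order`, `genotype`, `replicate`, `experiment_id`, `n_cells`.
#'   `n_cells` is present exactly for curve-standard wells; `genotype` and
#'   `replicate` may be empty for non-cell wells.
#' @name sample-table
NULL

.sample_types <- c("single_cell", "blank", "qc_pool", "curve_standard")

.sample_columns <- c("sample_id", "sample_type", "plate", "well",
                     "injection_order", "genotype", "replicate",
                     "experiment_id", "n_cells")

#' Validate a sample metadata table
#'
#' Checks column presence, unique sample ids, the sample-type enumeration,
#' and that `n_cells` is given if and only if the well is a curve standard.
#'
#' @param samples Data frame of well metadata.
#' @return The validated data frame (invisibly usable in pipelines).
#' @export
validate_samples <- function(samples) {
  samples <- assert_columns(samples, .sample_columns, "sample table")
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop_sclipid("sample table has duplicated sample_id(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", "),
                 class = "sclipid_validation_error")
  }
  bad <- setdiff(unique(samples$sample_type), .sample_types)
  if (length(bad) > 0L) {
    stop_sclipid("unknown sample_type(s): %s (known: %s)",
                 paste(bad, collapse = ", "),
                 paste(.sample_types, collapse = ", "),
                 class = "sclipid_validation_error")
  }
  is_curve <- samples$sample_type == "curve_standard"
  n_cells <- samples$n_cells
  if (any(is_curve & is.na(n_cells))) {
    stop_sclipid("curve_standard wells must have n_cells",
                 class = "sclipid_validation_error")
  }
  if (any(!is_curve & !is.na(n_cells))) {
    stop_sclipid("n_cells must be empty for non curve_standard wells",
                 class = "sclipid_validation_error")
  }
  samples
}

#' Read / write sample metadata CSV
#'
#' Empty fields and `"NA"` are read as missing. The column layout is fixed
#' (see \link{sample-table}).
#'
#' @param path CSV path.
#' @return `read_samples()` a validated data frame; `write_samples()` the
#'   path, invisibly.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) {
    stop_sclipid("sample table '%s' does not exist", path,
                 class = "sclipid_parse_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df$sample_id <- as.character(df$sample_id)
  df$plate <- as.integer(df$plate)
  df$injection_order <- as.integer(df$injection_order)
  df$n_cells <- as.integer(df$n_cells)
  for (col in c("genotype", "replicate", "experiment_id", "well")) {
    df[[col]] <- as.character(df[[col]])
  }
  validate_samples(df)
}

#' @rdname read_samples
#' @param samples A validated sample table.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}
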