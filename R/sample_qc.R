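#' @title Sample-level quality control
#' @description Classifies wells as usable single cells versus failed
#'   analyses (the extraction missed the cell: neither marker lipid
#'   detected) or doublets (two cells dispensed: almost all lipids
#'   inflated). Failed-well detection runs first; doublet detection runs on
#'   the raw (pre-normalization) abundances of the survivors, because
#'   total-signal normalization of a doublet would erase the doubling
#'   signature.
#' @name sample-qc
NULL

#' Failed-well detection from marker lipids
#'
#' A single-cell well fails only when *none* of the marker lipids is
#' detected (one detected marker suffices to pass). Blanks, pooled QCs and
#' curve wells are never classified as failed cells.
#'
#' @param matches Match table from [match_all()].
#' @param samples Sample metadata (see \link{sample-table}).
#' @param thresholds A [qc_thresholds()]; `marker_lipids` must all be
#'   present among the matched lipids.
#' @return Data frame with one row per single-cell sample: `sample_id`,
#'   one logical `marker_detected.<lipid>` column per marker, and `failed`.
#' @export
detect_failed <- function(matches, samples, thresholds = qc_thresholds()) {
  samples <- validate_samples(samples)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  markers <- thresholds$marker_lipids
  absent <- setdiff(markers, unique(matches$lipid_name))
  if (length(absent) > 0L) {
    stop_sclipid("marker lipid(s) not in the target panel: %s",
                 paste(absent, collapse = ", "),
                 class = "sclipid_config_error")
  }
  cells <- samples$sample_id[samples$sample_type == "single_cell"]
  sub <- matches[matches$sample_id %in% cells &
                   matches$lipid_name %in% markers, , drop = FALSE]
  det <- matrix(FALSE, nrow = length(cells), ncol = length(markers),
                dimnames = list(cells, markers))
  if (nrow(sub) > 0L) {
    det[cbind(match(sub$sample_id, cells), match(sub$lipid_name, markers))] <-
      sub$detected
  }
  out <- data.frame(sample_id = cells, stringsAsFactors = FALSE)
  for (m in markers) out[[paste0("marker_detected.", m)]] <- det[, m]
  out$failed <- rowSums(det) == 0L
  rownames(out) <- NULL
  out
}

#' Doublet detection by inflated raw abundances
#'
#' Per lipid, the mean and SD of raw intensity are computed over passing
#' single-cell wells of the reference population
#' (`thresholds$doublet_reference`: the same plate by default, or the whole
#' study). A sample is flagged as a doublet when the fraction of *its
#' detected lipids* lying above `mean + doublet_sd_multiplier x SD` is at
#' least `doublet_lipid_frac`. Because doublets sitting inside the
#' reference inflate the SD and mask one another, the reference is refined
#' iteratively: samples flagged in one pass are removed from the reference
#' and the statistics recomputed until the flagged set is stable
#' (`iterate = FALSE` gives the single-pass verdict). Blanks and QC wells
#' never enter the reference statistics. Reference groups with fewer than
#' 3 evaluable samples yield status `not_evaluable`, never a silent pass.
#'
#' @param raw Un-normalized [abundance_matrix()].
#' @param samples Sample metadata.
#' @param thresholds A [qc_thresholds()].
#' @param failed_ids Sample ids already excluded as failed wells (from
#'   [detect_failed()]).
#' @param iterate Refine the reference by excluding flagged doublets and
#'   recomputing until stable (default TRUE; at most 10 passes).
#' @return Data frame with one row per passing single-cell sample:
#'   `sample_id`, `doublet_fraction_high` (fraction of detected lipids
#'   above the cut, from the final reference), `n_detected`, `doublet`
#'   (logical), `status` (`"ok"` or `"not_evaluable"`).
#' @export
detect_doublets <- function(raw, samples, thresholds = qc_thresholds(),
                            failed_ids = character(), iterate = TRUE) {
  stopifnot(inherits(raw, "abundance_matrix"))
  if (raw$normalized) {
    stop_sclipid("doublet detection must run on the raw (un-normalized) matrix")
  }
  samples <- validate_samples(samples)
  cells <- samples[samples$sample_type == "single_cell" &
                     !(samples$sample_id %in% failed_ids), , drop = FALSE]
  cells <- cells[cells$sample_id %in% rownames(raw$values), , drop = FALSE]
  group <- switch(thresholds$doublet_reference,
                  plate = paste(cells$experiment_id, cells$plate),
                  global = rep("all", nrow(cells)))
  out <- data.frame(sample_id = cells$sample_id,
                    doublet_fraction_high = NA_real_,
                    n_detected = NA_integer_,
                    doublet = FALSE,
                    status = "ok",
                    stringsAsFactors = FALSE)
  for (g in unique(group)) {
    ids <- cells$sample_id[group == g]
    rows <- match(ids, out$sample_id)
    v <- raw$values[ids, , drop = FALSE]
    if (length(ids) < 3L) {
      out$status[rows] <- "not_evaluable"
      next
    }
    n_det <- rowSums(!is.na(v))
    flagged <- rep(FALSE, length(ids))
    frac <- rep(NA_real_, length(ids))
    max_pass <- if (iterate) 10L else 1L
    for (pass in seq_len(max_pass)) {
      ref <- v[!flagged, , drop = FALSE]
      if (nrow(ref) < 3L) break  # keep the last stable verdict
      mu <- colMeans(ref, na.rm = TRUE)
      sd <- apply(ref, 2L, stats::sd, na.rm = TRUE)
      cut <- mu + thresholds$doublet_sd_multiplier * sd
      high <- sweep(v, 2L, cut, ">")
      frac <- rowSums(high, na.rm = TRUE) / n_det
      frac[n_det == 0L] <- NA_real_
      new_flagged <- !is.na(frac) & frac >= thresholds$doublet_lipid_frac
      if (identical(new_flagged, flagged)) break
      flagged <- new_flagged
    }
    out$doublet_fraction_high[rows] <- frac
    out$n_detected[rows] <- n_det
    out$doublet[rows] <- flagged
    out$status[rows][n_det == 0L] <- "not_evaluable"
  }
  rownames(out) <- NULL
  out
}

#' Full sample-level QC report
#'
#' Runs failed-well detection, then doublet detection among the survivors,
#' and combines the verdicts into one status per single-cell sample.
#'
#' @param matches Match table from [match_all()].
#' @param raw Raw [abundance_matrix()] from [match_all()].
#' @param samples Sample metadata.
#' @param thresholds A [qc_thresholds()].
#' @return Data frame with `sample_id`, `status` (one of `pass`,
#'   `failed_no_marker`, `excluded_doublet`, `not_evaluable`),
#'   `doublet_fraction_high`, and the per-marker detection columns.
#' @export
sample_qc <- function(matches, raw, samples, thresholds = qc_thresholds()) {
  fails <- detect_failed(matches, samples, thresholds)
  failed_ids <- fails$sample_id[fails$failed]
  dbl <- detect_doublets(raw, samples, thresholds, failed_ids = failed_ids)
  out <- fails[, c("sample_id",
                   grep("^marker_detected\\.", names(fails), value = TRUE)),
               drop = FALSE]
  out$status <- "pass"
  out$status[fails$failed] <- "failed_no_marker"
  i <- match(dbl$sample_id, out$sample_id)
  out$doublet_fraction_high <- NA_real_
  out$doublet_fraction_high[i] <- dbl$doublet_fraction_high
  out$status[i[dbl$doublet]] <- "excluded_doublet"
  out$status[i[dbl$status == "not_evaluable"]] <- "not_evaluable"
  rownames(out) <- NULL
  out
}

#' Sample ids passing sample-level QC
#' @param qc Report from [sample_qc()].
#' @return Character vector of passing single-cell sample ids.
#' @export
passing_cells <- function(qc) qc$sample_id[qc$status == "pass"]
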