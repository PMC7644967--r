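#' @title Lipid-level quality control and confidence tiers
#' @description Within each experiment four filters decide whether a lipid
#'   was successfully measured: mass accuracy (median deviation of detected
#'   matches <= `ppm_max`), signal-to-noise (median S/N of detected matches
#'   > `snr_min`), cell standard-curve linearity (Pearson r > `curve_r_min`),
#'   and presence in at least `presence_min_frac` of passing single-cell
#'   samples (inclusive). Across experiments, lipids are graded into
#'   confidence tiers: level 1 = passed in all experiments, level 3 =
#'   passed in exactly one, level 2 = anything in between.
#' @name lipid-qc
NULL

#' Per-lipid presence fraction among passing cells
#'
#' @param matrix An [abundance_matrix()].
#' @param cells Character vector of passing single-cell sample ids
#'   (non-empty).
#' @return Named numeric vector: fraction of those cells in which each
#'   lipid has a detected (non-missing) value. Multiply by 100 for the
#'   percentages used in reports.
#' @export
presence_fraction <- function(matrix, cells) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (length(cells) == 0L) {
    stop_sclipid("presence_fraction requires a non-empty cell subset")
  }
  v <- subset_matrix(matrix, samples = cells)$values
  colMeans(!is.na(v))
}

#' Standard-curve linearity per lipid
#'
#' Pearson correlation between detected intensity and cell count over the
#' curve wells, missing values pairwise-dropped. Not evaluable (NA) when
#' fewer than 3 paired points remain, fewer than 3 distinct cell-count
#' levels are covered, or the intensity vector is constant.
#'
#' @param curve_matrix [abundance_matrix()] restricted to curve wells.
#' @param cell_counts Integer vector of cell counts, one per row of
#'   `curve_matrix` (same order).
#' @return Named numeric vector of Pearson r (NA = not evaluable).
#' @export
curve_linearity <- function(curve_matrix, cell_counts) {
  stopifnot(inherits(curve_matrix, "abundance_matrix"))
  v <- curve_matrix$values
  if (length(cell_counts) != nrow(v)) {
    stop_sclipid("cell_counts must have one entry per curve well")
  }
  apply(v, 2L, function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 3L || length(unique(cell_counts[ok])) < 3L) return(NA_real_)
    if (stats::sd(y[ok]) == 0 || stats::sd(cell_counts[ok]) == 0) return(NA_real_)
    stats::cor(cell_counts[ok], y[ok])
  })
}

#' Apply the four lipid-level QC filters for one experiment
#'
#' @param matches Match table from [match_all()] (this experiment's wells).
#' @param raw Raw [abundance_matrix()] for the same wells.
#' @param samples Sample metadata for the experiment.
#' @param cells Passing single-cell sample ids (from [sample_qc()]).
#' @param thresholds A [qc_thresholds()].
#' @param experiment_id Label recorded in the report; default taken from
#'   the sample table.
#' @param aggregate `"median"` (default, robust) or `"mean"`: how per-match
#'   deviation and S/N are summarised per lipid before thresholding.
#' @return A `LipidQCReport` data frame: `lipid_name`, `experiment_id`,
#'   `median_deviation_ppm`, `median_snr`, `within_ppm`, `snr_pass`,
#'   `curve_r`, `curve_pass`, `presence_frac`, `presence_pass`, `passes`
#'   (the conjunction of the four filters).
#' @export
apply_filters <- function(matches, raw, samples, cells,
                          thresholds = qc_thresholds(),
                          experiment_id = NULL,
                          aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  samples <- validate_samples(samples)
  stopifnot(inherits(raw, "abundance_matrix"))
  if (is.null(experiment_id)) {
    experiment_id <- unique(samples$experiment_id)
    if (length(experiment_id) != 1L) {
      stop_sclipid("samples span several experiment_ids; call per experiment or set experiment_id")
    }
  }
  if (length(cells) == 0L) {
    stop_sclipid("no passing single-cell samples for experiment '%s'",
                 experiment_id)
  }
  lipids <- unique(matches$lipid_name)
  cell_matches <- matches[matches$sample_id %in% cells, , drop = FALSE]

  pres <- presence_fraction(raw, cells)[lipids]

  curve_wells <- samples[samples$sample_type == "curve_standard", , drop = FALSE]
  curve_r <- stats::setNames(rep(NA_real_, length(lipids)), lipids)
  if (nrow(curve_wells) > 0L) {
    cm <- subset_matrix(raw, samples = curve_wells$sample_id)
    curve_r[lipids] <- curve_linearity(cm, curve_wells$n_cells)[lipids]
  }

  out <- lapply(lipids, function(lip) {
    sub <- cell_matches[cell_matches$lipid_name == lip & cell_matches$detected, ,
                        drop = FALSE]
    med_dev <- if (nrow(sub) > 0L) agg(sub$deviation_ppm) else NA_real_
    med_snr <- if (nrow(sub) > 0L) agg(sub$snr) else NA_real_
    within_ppm <- !is.na(med_dev) && med_dev <= thresholds$ppm_max
    snr_pass <- !is.na(med_snr) && med_snr > thresholds$snr_min
    curve_pass <- !is.na(curve_r[[lip]]) && curve_r[[lip]] > thresholds$curve_r_min
    presence_pass <- pres[[lip]] >= thresholds$presence_min_frac
    data.frame(lipid_name = lip,
               experiment_id = experiment_id,
               median_deviation_ppm = med_dev,
               median_snr = med_snr,
               within_ppm = within_ppm,
               snr_pass = snr_pass,
               curve_r = curve_r[[lip]],
               curve_pass = curve_pass,
               presence_frac = pres[[lip]],
               presence_pass = presence_pass,
               passes = within_ppm && snr_pass && curve_pass && presence_pass,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign cross-experiment confidence tiers
#'
#' With E experiments: level 1 = passed all E, level 3 = passed exactly
#' one, level 2 = anything in between (with E = 3 this is the usual
#' "all three / two of three / one only" grading). Lipids passing zero
#' experiments are dropped and counted.
#'
#' @param reports Either one data frame with columns `lipid_name`,
#'   `experiment_id`, `passes` (e.g. several [apply_filters()] outputs
#'   row-bound), or a list of such data frames.
#' @return A `TierTable` data frame: `lipid_name`, `n_experiments_passed`,
#'   `level`, with attributes `n_experiments` and `n_dropped`.
#' @export
assign_tiers <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  reports <- assert_columns(reports, c("lipid_name", "experiment_id", "passes"),
                            "tier input")
  n_exp <- length(unique(reports$experiment_id))
  if (n_exp < 1L) stop_sclipid("assign_tiers needs at least one experiment")
  passed <- reports[reports$passes, , drop = FALSE]
  lipids <- sort(unique(reports$lipid_name))
  n_passed <- vapply(lipids, function(lip) {
    length(unique(passed$experiment_id[passed$lipid_name == lip]))
  }, 0L)
  dropped <- sum(n_passed == 0L)
  keep <- n_passed > 0L
  lipids <- lipids[keep]
  n_passed <- n_passed[keep]
  level <- ifelse(n_passed == n_exp, 1L, ifelse(n_passed == 1L, 3L, 2L))
  # with a single experiment "all" wins over "exactly one"
  out <- data.frame(lipid_name = lipids,
                    n_experiments_passed = n_passed,
                    level = level,
                    stringsAsFactors = FALSE)
  ord <- order(out$level, out$lipid_name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_experiments") <- n_exp
  attr(out, "n_dropped") <- dropped
  out
}

#' Tier assignment from a presence-percentage table
#'
#' Convenience front-end for published presence tables: a lipids x
#' experiments matrix of "percentage of cells in which the lipid was
#' measured" is thresholded at `min_pct` (inclusive: "at least 5%" keeps a
#' 5.0% entry) and passed to [assign_tiers()]. The other three filters are
#' taken as already applied upstream of such a table.
#'
#' @param presence Numeric matrix, rownames = lipid names, colnames =
#'   experiment ids, values = presence percentages (0-100).
#' @param min_pct Inclusive presence threshold in percent. Default 5.
#' @return A tier table (see [assign_tiers()]).
#' @export
tiers_from_presence <- function(presence, min_pct = 5) {
  if (!is.matrix(presence) || is.null(rownames(presence)) ||
      is.null(colnames(presence))) {
    stop_sclipid("presence must be a matrix with lipid rownames and experiment colnames")
  }
  long <- expand.grid(lipid_name = rownames(presence),
                      experiment_id = colnames(presence),
                      stringsAsFactors = FALSE)
  long$passes <- as.vector(presence) >= min_pct
  assign_tiers(long)
}
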