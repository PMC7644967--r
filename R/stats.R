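#' @title Single-cell heterogeneity statistics
#' @description Downstream comparisons on normalized profiles: population
#'   (per-replicate mean) profiles, per-lipid genotype contrasts via a
#'   Gaussian linear model on log abundance, stratification of cells by the
#'   abundance of a reference lipid (median split within genotype),
#'   high-vs-low contrasts with fold changes relative to the low stratum,
#'   and the total PC / total PE ratio.
#' @name heterogeneity-stats
NULL

#' Population (per-replicate mean) lipid profiles
#'
#' The mean abundance of each lipid over the single cells of each
#' (genotype, replicate), detected values only. A lipid missing in every
#' cell of a replicate stays missing in the profile. Replicates without
#' cells are dropped with a warning.
#'
#' @param matrix An [abundance_matrix()] (typically normalized).
#' @param samples Sample metadata.
#' @param cells Optional subset of single-cell sample ids (e.g. QC-passing
#'   cells); default all single cells present in the matrix.
#' @return A list with `profiles` (an [abundance_matrix()] with one row
#'   per "genotype.replicate") and `n_cells` (named count per profile).
#' @export
population_profiles <- function(matrix, samples, cells = NULL) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  samples <- validate_samples(samples)
  sc <- samples[samples$sample_type == "single_cell", , drop = FALSE]
  if (!is.null(cells)) sc <- sc[sc$sample_id %in% cells, , drop = FALSE]
  sc <- sc[sc$sample_id %in% rownames(matrix$values), , drop = FALSE]
  if (nrow(sc) == 0L) stop_sclipid("no single-cell samples to profile")
  grp <- paste(sc$genotype, sc$replicate, sep = ".")
  groups <- unique(grp)
  prof <- matrix(NA_real_, nrow = length(groups), ncol = ncol(matrix$values),
                 dimnames = list(groups, colnames(matrix$values)))
  n <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    ids <- sc$sample_id[grp == g]
    n[[g]] <- length(ids)
    v <- matrix$values[ids, , drop = FALSE]
    m <- colMeans(v, na.rm = TRUE)
    m[colSums(!is.na(v)) == 0L] <- NA_real_
    prof[g, ] <- m
  }
  empty <- n == 0L
  if (any(empty)) {
    warning(sprintf("dropping replicate(s) with zero cells: %s",
                    paste(groups[empty], collapse = ", ")))
    prof <- prof[!empty, , drop = FALSE]
    n <- n[!empty]
  }
  list(profiles = abundance_matrix(prof, normalized = FALSE), n_cells = n)
}

#' Two-group contrast of one variable (Gaussian linear model)
#'
#' Fits a Gaussian-family linear model of the (by default log-transformed)
#' values on group membership and reports the two-sided Wald p-value of the
#' group coefficient, together with the fold change of group means on the
#' natural scale relative to the reference group. With a single binary
#' covariate this is equivalent to a two-sample t test (equal variances).
#' Non-positive values cannot be log-transformed and are treated as
#' missing on the log scale.
#'
#' @param values Numeric vector (abundances; NA = not detected).
#' @param group Factor/character of the same length with exactly two
#'   levels present.
#' @param reference Reference level; default the first of `sort(unique)`.
#' @param log_scale Model log-transformed values (default TRUE; set FALSE
#'   for the identity link on the raw scale).
#' @param variable Name recorded in the output.
#' @return One-row `GroupComparison` data frame: `variable`, `group`,
#'   `reference`, `n_ref`, `n_alt`, `mean_ref`, `mean_alt`, `sd_ref`,
#'   `sd_alt`, `fold_change` (mean_alt / mean_ref), `p_value`, `status`
#'   (`"ok"` or `"not_evaluable"` — degenerate inputs give NA p, never NaN).
#' @export
group_test <- function(values, group, reference = NULL, log_scale = TRUE,
                       variable = "variable") {
  ok <- !is.na(values) & !is.na(group)
  if (log_scale) ok <- ok & values > 0
  values <- values[ok]
  group <- as.character(group)[ok]
  levels <- sort(unique(group))
  out <- data.frame(variable = variable,
                    group = NA_character_, reference = NA_character_,
                    n_ref = NA_integer_, n_alt = NA_integer_,
                    mean_ref = NA_real_, mean_alt = NA_real_,
                    sd_ref = NA_real_, sd_alt = NA_real_,
                    fold_change = NA_real_, p_value = NA_real_,
                    status = "not_evaluable", stringsAsFactors = FALSE)
  if (length(levels) != 2L) return(out)
  if (is.null(reference)) reference <- levels[1L]
  if (!reference %in% levels) {
    stop_sclipid("reference group '%s' absent from data", reference)
  }
  alt <- setdiff(levels, reference)
  x_ref <- values[group == reference]
  x_alt <- values[group == alt]
  out$group <- alt
  out$reference <- reference
  out$n_ref <- length(x_ref)
  out$n_alt <- length(x_alt)
  if (length(x_ref) < 3L || length(x_alt) < 3L) return(out)
  out$mean_ref <- mean(x_ref)
  out$mean_alt <- mean(x_alt)
  out$sd_ref <- stats::sd(x_ref)
  out$sd_alt <- stats::sd(x_alt)
  out$fold_change <- out$mean_alt / out$mean_ref
  y <- if (log_scale) log(values) else values
  if (stats::sd(y) == 0) {
    # all values identical in both groups: no evidence of difference
    out$p_value <- 1
    out$status <- "ok"
    return(out)
  }
  g <- factor(group, levels = c(reference, alt))
  fit <- stats::lm(y ~ g)
  coefs <- summary(fit)$coefficients
  if (nrow(coefs) < 2L || !is.finite(coefs[2L, 4L])) return(out)
  out$p_value <- coefs[2L, 4L]
  out$status <- "ok"
  out
}

#' Per-lipid genotype contrasts
#'
#' Runs [group_test()] for every lipid (and optionally the PC/PE ratio) on
#' the single-cell samples, comparing genotypes. Benjamini-Hochberg
#' q-values are reported alongside the raw p-values.
#'
#' @param matrix Normalized [abundance_matrix()].
#' @param samples Sample metadata.
#' @param cells Optional subset of passing cell ids.
#' @param targets Optional target panel; when given, a `"PC/PE"` row (total
#'   PC over total PE per cell) is included.
#' @param reference Reference genotype; default the first alphabetically.
#' @param log_scale Passed to [group_test()].
#' @return Data frame of `GroupComparison` rows plus `q_value`.
#' @export
genotype_tests <- function(matrix, samples, cells = NULL, targets = NULL,
                           reference = NULL, log_scale = TRUE) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  samples <- validate_samples(samples)
  sc <- samples[samples$sample_type == "single_cell", , drop = FALSE]
  if (!is.null(cells)) sc <- sc[sc$sample_id %in% cells, , drop = FALSE]
  sc <- sc[sc$sample_id %in% rownames(matrix$values), , drop = FALSE]
  v <- matrix$values[sc$sample_id, , drop = FALSE]
  res <- lapply(colnames(v), function(lip) {
    group_test(v[, lip], sc$genotype, reference = reference,
               log_scale = log_scale, variable = lip)
  })
  if (!is.null(targets)) {
    ratio <- pc_pe_ratio(subset_matrix(matrix, samples = sc$sample_id), targets)
    res <- c(res, list(group_test(ratio, sc$genotype, reference = reference,
                                  log_scale = log_scale, variable = "PC/PE")))
  }
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Stratify cells by the abundance of one lipid
#'
#' Default rule: median split on the (normalized) abundance within each
#' genotype; ties at the median go to the low stratum; cells in which the
#' lipid is missing are unassigned and excluded.
#'
#' @param matrix Normalized [abundance_matrix()].
#' @param samples Sample metadata.
#' @param lipid Lipid to stratify by. Default `"PC 36:2"`.
#' @param cells Optional subset of passing cell ids.
#' @param by_genotype Split within genotype (default TRUE) or pooled.
#' @return A `StratifiedCohort` data frame: `sample_id`, `genotype`,
#'   `stratum` (`"high"`/`"low"`), with attributes `rule`, `lipid` and
#'   `thresholds` (the median(s) used). Errors when fewer than 4 assignable
#'   cells exist in some genotype.
#' @export
stratify_by_lipid <- function(matrix, samples, lipid = "PC 36:2",
                              cells = NULL, by_genotype = TRUE) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  samples <- validate_samples(samples)
  if (!lipid %in% colnames(matrix$values)) {
    stop_sclipid("lipid '%s' is not in the matrix", lipid)
  }
  sc <- samples[samples$sample_type == "single_cell", , drop = FALSE]
  if (!is.null(cells)) sc <- sc[sc$sample_id %in% cells, , drop = FALSE]
  sc <- sc[sc$sample_id %in% rownames(matrix$values), , drop = FALSE]
  x <- matrix$values[sc$sample_id, lipid]
  assignable <- !is.na(x)
  sc <- sc[assignable, , drop = FALSE]
  x <- x[assignable]
  grp <- if (by_genotype) sc$genotype else rep("all", nrow(sc))
  thresholds <- c()
  stratum <- rep(NA_character_, nrow(sc))
  degenerate <- FALSE
  for (g in unique(grp)) {
    idx <- grp == g
    if (sum(idx) < 4L) {
      stop_sclipid("genotype '%s' has %d assignable cells (>= 4 required)",
                   g, sum(idx))
    }
    med <- stats::median(x[idx])
    thresholds[g] <- med
    stratum[idx] <- ifelse(x[idx] > med, "high", "low")
    if (all(x[idx] == x[idx][1L])) degenerate <- TRUE
  }
  out <- data.frame(sample_id = sc$sample_id, genotype = sc$genotype,
                    stratum = stratum, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rule") <- sprintf("median split %s; ties to low",
                               if (by_genotype) "within genotype" else "pooled")
  attr(out, "lipid") <- lipid
  attr(out, "thresholds") <- thresholds
  attr(out, "degenerate") <- degenerate
  out
}

#' High-vs-low contrasts within each genotype
#'
#' Applies the [group_test()] machinery to every lipid (and the PC/PE
#' ratio when `targets` is given) comparing the high against the low
#' stratum within each genotype. Fold changes are relative to the low
#' stratum; Benjamini-Hochberg q-values are reported within genotype.
#'
#' @param matrix Normalized [abundance_matrix()].
#' @param cohort A `StratifiedCohort` from [stratify_by_lipid()].
#' @param targets Optional target panel enabling the `"PC/PE"` row.
#' @param log_scale Passed to [group_test()].
#' @return Data frame of `GroupComparison` rows with `genotype` and
#'   `q_value` columns; `fold_change` is mean(high) / mean(low).
#' @export
stratified_tests <- function(matrix, cohort, targets = NULL,
                             log_scale = TRUE) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  cohort <- assert_columns(cohort, c("sample_id", "genotype", "stratum"),
                           "stratified cohort")
  out <- lapply(unique(cohort$genotype), function(g) {
    sub <- cohort[cohort$genotype == g, , drop = FALSE]
    v <- matrix$values[sub$sample_id, , drop = FALSE]
    res <- lapply(colnames(v), function(lip) {
      group_test(v[, lip], sub$stratum, reference = "low",
                 log_scale = log_scale, variable = lip)
    })
    if (!is.null(targets)) {
      ratio <- pc_pe_ratio(subset_matrix(matrix, samples = sub$sample_id),
                           targets)
      res <- c(res, list(group_test(ratio, sub$stratum, reference = "low",
                                    log_scale = log_scale,
                                    variable = "PC/PE")))
    }
    res <- do.call(rbind, res)
    res$genotype <- g
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample ratio of total PC to total PE
#'
#' Sum of detected PC-class values over the sum of detected PE-class
#' values. Samples with no detected PE (or no detected PC) are not
#' evaluable (NA). Because numerator and denominator share any per-sample
#' scale factor, the ratio is invariant to total-signal normalization.
#'
#' @param matrix An [abundance_matrix()].
#' @param targets Target panel mapping lipid names to classes.
#' @return Named numeric vector, one entry per sample.
#' @export
pc_pe_ratio <- function(matrix, targets) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  targets <- .validate_targets(targets)
  pcs <- intersect(targets$name[targets$lipid_class == "PC"],
                   colnames(matrix$values))
  pes <- intersect(targets$name[targets$lipid_class == "PE"],
                   colnames(matrix$values))
  v <- matrix$values
  num <- rowSums(v[, pcs, drop = FALSE], na.rm = TRUE)
  den <- rowSums(v[, pes, drop = FALSE], na.rm = TRUE)
  n_pc <- rowSums(!is.na(v[, pcs, drop = FALSE]))
  n_pe <- rowSums(!is.na(v[, pes, drop = FALSE]))
  out <- num / den
  out[n_pc == 0L | n_pe == 0L | den == 0] <- NA_real_
  stats::setNames(out, rownames(v))
}
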