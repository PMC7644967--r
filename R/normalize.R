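#' @title Total-signal normalization and batch checks
#' @description Cell size is the dominant driver of measured lipid
#'   abundance: a larger cell carries more of every lipid. Dividing each
#'   sample by its total detected signal removes this size component (and
#'   any other per-sample multiplicative factor, including plate batch
#'   effects), leaving unit-sum composition profiles. The batch checks
#'   verify, on the pooled QC wells, that between-plate differences present
#'   in the raw data vanish after normalization, and that lipid composition
#'   carries no injection-order trend.
#' @name normalization
NULL

#' Normalize each sample to its total detected signal
#'
#' Each detected value is divided by the sum of detected values in its
#' sample; missing stays missing; non-missing values of every row then sum
#' to 1. The operation is idempotent and invariant to any per-sample
#' positive rescaling.
#'
#' @param raw An [abundance_matrix()].
#' @return A normalized [abundance_matrix()] (flag set).
#' @examples
#' m <- abundance_matrix(matrix(c(2, 3, 5), 1, 3,
#'   dimnames = list("s1", c("a", "b", "c"))))
#' as.matrix(total_signal_normalize(m))
#' @export
total_signal_normalize <- function(raw) {
  stopifnot(inherits(raw, "abundance_matrix"))
  v <- raw$values
  totals <- rowSums(v, na.rm = TRUE)
  n_det <- rowSums(!is.na(v))
  if (any(n_det == 0L | totals <= 0)) {
    bad <- rownames(v)[n_det == 0L | totals <= 0][1L]
    stop_sclipid("sample '%s' has no detected signal to normalize (exclude it upstream)",
                 bad, class = "sclipid_validation_error")
  }
  abundance_matrix(v / totals, normalized = TRUE)
}

#' Between-plate batch-effect check on pooled QC wells
#'
#' Per lipid, a one-way between-plate test (ANOVA by default, or
#' Kruskal-Wallis) is run on the pooled-QC wells, once on the raw and once
#' on the normalized values. A lipid whose raw p-value is below `alpha`
#' while its normalized p-value is not is flagged as a corrected batch
#' effect. Plates with fewer than 2 QC wells are dropped with a warning;
#' lipids with no variance across QCs get p = 1.
#'
#' @param raw Raw [abundance_matrix()] (all wells; QC wells are selected
#'   via `samples`).
#' @param normalized Normalized matrix; default
#'   `total_signal_normalize(raw)` restricted to the QC wells.
#' @param samples Sample metadata.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @param alpha Significance level. Default 0.05.
#' @return Data frame per lipid: `lipid_name`, `p_raw`, `p_normalized`,
#'   `raw_significant`, `normalized_significant`, `batch_effect_removed`;
#'   attribute `plate_means` holds per-plate QC means (raw and normalized).
#' @export
plate_batch_check <- function(raw, samples, normalized = NULL,
                              method = c("anova", "kruskal"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(raw, "abundance_matrix"))
  samples <- validate_samples(samples)
  qc <- samples[samples$sample_type == "qc_pool", , drop = FALSE]
  qc <- qc[qc$sample_id %in% rownames(raw$values), , drop = FALSE]
  counts <- table(qc$plate)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warning(sprintf("dropping plate(s) with < 2 QC wells: %s",
                    paste(small, collapse = ", ")))
    qc <- qc[!(as.character(qc$plate) %in% small), , drop = FALSE]
  }
  if (length(unique(qc$plate)) < 2L) {
    stop_sclipid("plate_batch_check needs >= 2 plates with >= 2 QC wells each")
  }
  raw_qc <- subset_matrix(raw, samples = qc$sample_id)
  norm_qc <- if (is.null(normalized)) {
    total_signal_normalize(raw_qc)
  } else {
    subset_matrix(normalized, samples = qc$sample_id)
  }
  plate <- factor(qc$plate)

  test_p <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 3L || length(unique(plate[ok])) < 2L) return(NA_real_)
    if (stats::sd(y[ok]) == 0) return(1)
    if (method == "anova") {
      fit <- stats::aov(y[ok] ~ plate[ok])
      p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      if (is.na(p)) 1 else p
    } else {
      stats::kruskal.test(y[ok], plate[ok])$p.value
    }
  }
  lipids <- colnames(raw_qc$values)
  p_raw <- vapply(lipids, function(l) test_p(raw_qc$values[, l]), 0)
  p_norm <- vapply(lipids, function(l) test_p(norm_qc$values[, l]), 0)
  out <- data.frame(lipid_name = lipids,
                    p_raw = p_raw,
                    p_normalized = p_norm,
                    raw_significant = !is.na(p_raw) & p_raw < alpha,
                    normalized_significant = !is.na(p_norm) & p_norm < alpha,
                    stringsAsFactors = FALSE)
  out$batch_effect_removed <- out$raw_significant & !out$normalized_significant
  rownames(out) <- NULL
  pm_raw <- t(vapply(lipids, function(l) {
    tapply(raw_qc$values[, l], plate, mean, na.rm = TRUE)
  }, stats::setNames(numeric(nlevels(plate)), levels(plate))))
  attr(out, "plate_means") <- pm_raw
  out
}

# per-lipid minimum / 2 imputation of missing values, for ordination only
.impute_min2 <- function(v) {
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (all(miss)) {
      v[, j] <- 0
    } else if (any(miss)) {
      v[miss, j] <- min(v[, j], na.rm = TRUE) / 2
    }
  }
  v
}

#' Injection-order association of the lipid composition
#'
#' Principal components of the (missing-imputed, per-lipid minimum / 2)
#' normalized profiles are correlated with injection order by Spearman's
#' rho, with permutation p-values. With no drift the first two component
#' scores are unrelated to the run order.
#'
#' @param matrix Normalized [abundance_matrix()] of the samples to check.
#' @param samples Sample metadata (provides `injection_order`).
#' @param n_components Number of leading components tested. Default 2.
#' @param n_perm Permutations for the p-value. Default 999.
#' @param seed Seed for the permutations. Default 1.
#' @return Data frame per component: `component`, `spearman_rho`
#'   (0 by convention for a constant score vector), `p_value`; or status
#'   `not_evaluable` (attribute) with an all-NA frame when < 3 samples.
#' @export
injection_order_check <- function(matrix, samples, n_components = 2L,
                                  n_perm = 999L, seed = 1L) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  samples <- validate_samples(samples)
  ids <- intersect(rownames(matrix$values), samples$sample_id)
  ord <- samples$injection_order[match(ids, samples$sample_id)]
  if (length(ids) < 3L) {
    out <- data.frame(component = seq_len(n_components),
                      spearman_rho = NA_real_, p_value = NA_real_)
    attr(out, "status") <- "not_evaluable"
    return(out)
  }
  v <- .impute_min2(matrix$values[ids, , drop = FALSE])
  keep <- apply(v, 2L, function(x) stats::sd(x) > 0)
  pc <- stats::prcomp(v[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  out <- with_seed(seed, {
    res <- lapply(seq_len(k), function(j) {
      sc <- pc$x[, j]
      if (stats::sd(sc) == 0) {
        return(data.frame(component = j, spearman_rho = 0, p_value = 1))
      }
      rho <- stats::cor(sc, ord, method = "spearman")
      perm <- vapply(seq_len(n_perm), function(i) {
        stats::cor(sc, sample(ord), method = "spearman")
      }, 0)
      p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
      data.frame(component = j, spearman_rho = rho, p_value = p)
    })
    do.call(rbind, res)
  })
  attr(out, "status") <- "ok"
  out
}
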