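#' @title Signal matching
#' @description For each target lipid in each spectrum, find the closest
#'   peak, quantify its mass deviation in ppm, intensity and local
#'   signal-to-noise ratio, and decide detection. Deviations are reported
#'   unsigned: ppm deviation = |observed - target| / target x 1e6.
#' @name signal-matching
NULL

#' Closest peak to a target m/z within a ppm window
#'
#' Returns the peak minimising the absolute m/z distance to the target
#' among peaks within `window_ppm`; ties on distance are broken toward
#' higher intensity, then lower m/z. Peaks are assumed sorted ascending
#' (as produced by [spectrum()]); the search is a binary bracket, not a
#' linear scan.
#'
#' @param spec A [spectrum()].
#' @param target_mz Target m/z (Da).
#' @param window_ppm Half-width of the search window in ppm (use `Inf` for
#'   a global closest-peak search, as in blank assessment).
#' @return A list with `mz`, `intensity`, `deviation_ppm`, or `NULL` when
#'   no peak falls inside the window (including the empty spectrum).
#' @examples
#' sp <- spectrum("s", c(760.5851, 760.59), c(100, 5))
#' closest_peak(sp, 760.5851, 10)
#' @export
closest_peak <- function(spec, target_mz, window_ppm) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.finite(target_mz) || target_mz <= 0) {
    stop_sclipid("target_mz must be positive")
  }
  if (!(window_ppm > 0)) {
    stop_sclipid("window_ppm must be > 0")
  }
  mz <- spec$peaks$mz
  n <- length(mz)
  if (n == 0L) return(NULL)
  tol_da <- if (is.finite(window_ppm)) window_ppm * target_mz / 1e6 else Inf
  # bracket the insertion point, then widen to absorb exact ties
  pos <- findInterval(target_mz, mz)
  cand <- unique(pmin(pmax(c(pos, pos + 1L), 1L), n))
  d <- abs(mz[cand] - target_mz)
  dmin <- min(d)
  if (dmin > tol_da) return(NULL)
  # all peaks at distance dmin (duplicated m/z values are allowed)
  lo <- pos
  while (lo >= 1L && abs(mz[lo] - target_mz) <= dmin + 1e-12) lo <- lo - 1L
  hi <- pos + 1L
  while (hi <= n && abs(mz[hi] - target_mz) <= dmin + 1e-12) hi <- hi + 1L
  idx <- seq.int(lo + 1L, hi - 1L)
  idx <- idx[abs(mz[idx] - target_mz) <= dmin * (1 + 1e-12)]
  if (length(idx) > 1L) {
    it <- spec$peaks$intensity[idx]
    idx <- idx[it == max(it)]
    if (length(idx) > 1L) idx <- idx[which.min(mz[idx])]
  }
  list(mz = mz[idx],
       intensity = spec$peaks$intensity[idx],
       deviation_ppm = abs(mz[idx] - target_mz) / target_mz * 1e6)
}

#' Local signal-to-noise ratio of a matched peak
#'
#' Noise is the median intensity of the *other* peaks within
#' `noise_window_da` of the peak m/z. If no such neighbours exist the
#' noise falls back to the 5th percentile of all peak intensities in the
#' spectrum; if that is 0 (or there are no other peaks at all) the S/N is
#' `+Inf`.
#'
#' @param spec A [spectrum()].
#' @param peak A list or vector with elements `mz` and `intensity`
#'   identifying a peak of `spec` (exact match required).
#' @param noise_window_da Half-width in Da of the local noise window.
#'   Default 0.5 (the same nominal-mass channel).
#' @return The signal-to-noise ratio (>= 0, possibly `Inf`).
#' @export
estimate_snr <- function(spec, peak, noise_window_da = 0.5) {
  stopifnot(inherits(spec, "spectrum"))
  assert_scalar_number(noise_window_da, "noise_window_da",
                       lower = .Machine$double.eps)
  mz <- spec$peaks$mz
  it <- spec$peaks$intensity
  hit <- which(mz == peak$mz & it == peak$intensity)
  if (length(hit) == 0L) {
    stop_sclipid("peak (%.5f, %g) is not part of spectrum '%s'",
                 peak$mz, peak$intensity, spec$sample_id)
  }
  hit <- hit[1L]
  neighbours <- which(abs(mz - peak$mz) <= noise_window_da)
  neighbours <- setdiff(neighbours, hit)
  noise <- if (length(neighbours) > 0L) {
    stats::median(it[neighbours])
  } else if (length(it) > 1L) {
    stats::quantile(it, probs = 0.05, names = FALSE)
  } else {
    0
  }
  if (noise <= 0) return(Inf)
  it[hit] / noise
}

#' Match every target lipid in every spectrum
#'
#' Produces one match record per (sample, lipid): the closest peak within
#' `ppm_max`, its unsigned ppm deviation, intensity and S/N, and the
#' detection verdict `deviation_ppm <= ppm_max AND snr > snr_min`. Also
#' returns the raw abundance matrix: intensity where detected, `NA`
#' otherwise (the `normalized` flag is `FALSE`).
#'
#' @param spectra List of [spectrum()] objects.
#' @param targets Target panel data frame.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `matches` (data frame with columns `sample_id`,
#'   `lipid_name`, `measured_mz`, `deviation_ppm` (+Inf when no peak in
#'   window), `intensity`, `snr`, `detected`) and `raw`
#'   (an [abundance_matrix()]).
#' @export
match_all <- function(spectra, targets, thresholds = qc_thresholds()) {
  targets <- .validate_targets(targets)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (nrow(targets) == 0L) {
    stop_sclipid("targets must be non-empty")
  }
  n_s <- length(spectra)
  n_l <- nrow(targets)
  ids <- vapply(spectra, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop_sclipid("duplicate sample_id among spectra",
                 class = "sclipid_validation_error")
  }
  res <- vector("list", n_s)
  raw <- matrix(NA_real_, nrow = n_s, ncol = n_l,
                dimnames = list(ids, targets$name))
  for (i in seq_len(n_s)) {
    sp <- spectra[[i]]
    measured <- rep(NA_real_, n_l)
    dev <- rep(Inf, n_l)
    inten <- rep(NA_real_, n_l)
    snr <- rep(NA_real_, n_l)
    det <- rep(FALSE, n_l)
    for (j in seq_len(n_l)) {
      hit <- closest_peak(sp, targets$target_mz[j], thresholds$ppm_max)
      if (is.null(hit)) next
      measured[j] <- hit$mz
      dev[j] <- hit$deviation_ppm
      inten[j] <- hit$intensity
      snr[j] <- estimate_snr(sp, hit, thresholds$noise_window_da)
      det[j] <- dev[j] <= thresholds$ppm_max && snr[j] > thresholds$snr_min
      if (det[j]) raw[i, j] <- inten[j]
    }
    res[[i]] <- data.frame(sample_id = sp$sample_id,
                           lipid_name = targets$name,
                           measured_mz = measured,
                           deviation_ppm = dev,
                           intensity = inten,
                           snr = snr,
                           detected = det,
                           stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, res)
  rownames(matches) <- NULL
  list(matches = matches, raw = abundance_matrix(raw, normalized = FALSE))
}

#' Closest-signal deviation statistics in extraction blanks
#'
#' For each marker lipid, the globally closest peak (no ppm window) in
#' every blank spectrum is found and its deviation summarised: the blank
#' noise floor should sit far from the target mass while true cell signals
#' sit within a few ppm. Blanks with no peaks at all are excluded from the
#' mean and counted as non-evaluable.
#'
#' @param spectra List of [spectrum()] objects (the blank wells).
#' @param targets Target panel restricted to the lipids of interest
#'   (typically the marker lipids).
#' @param ppm_max Window used only for the "within window" count.
#'   Default 10.
#' @return Data frame with one row per target: `lipid_name`,
#'   `mean_closest_deviation_ppm`, `min_deviation_ppm`, `n_within_ppm_max`,
#'   `n_blanks`, `n_non_evaluable`.
#' @export
blank_assessment <- function(spectra, targets, ppm_max = 10) {
  targets <- .validate_targets(targets)
  if (length(spectra) == 0L) {
    stop_sclipid("blank_assessment requires at least one blank spectrum")
  }
  out <- lapply(seq_len(nrow(targets)), function(j) {
    devs <- vapply(spectra, function(sp) {
      hit <- closest_peak(sp, targets$target_mz[j], Inf)
      if (is.null(hit)) NA_real_ else hit$deviation_ppm
    }, 0)
    ok <- !is.na(devs)
    data.frame(
      lipid_name = targets$name[j],
      mean_closest_deviation_ppm = if (any(ok)) mean(devs[ok]) else NA_real_,
      min_deviation_ppm = if (any(ok)) min(devs[ok]) else NA_real_,
      n_within_ppm_max = sum(devs[ok] <= ppm_max),
      n_blanks = length(spectra),
      n_non_evaluable = sum(!ok),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
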