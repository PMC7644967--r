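#' Quality-control thresholds for the filter cascade
#'
#' Bundles every tunable parameter of the QC cascade in one object. The
#' defaults are the relaxed single-cell cutoffs used throughout the package:
#' a 10 ppm mass-accuracy window, signal-to-noise above 1.5, standard-curve
#' Pearson r above 0.5, presence in at least 5% of passing single-cell
#' samples, and the doublet rule flagging wells in which at least 80% of
#' detected lipids lie more than 2.5 standard deviations above the
#' single-cell mean.
#'
#' @param ppm_max Maximum mass deviation (ppm) for a peak to count as the
#'   target lipid. Default 10.
#' @param snr_min Signal-to-noise ratio a matched peak must strictly exceed.
#'   Default 1.5.
#' @param curve_r_min Pearson correlation between signal and cell number in
#'   the cell standard curve that a lipid must strictly exceed. Default 0.5.
#' @param presence_min_frac Minimum fraction of passing single-cell samples
#'   in which a lipid must be detected (inclusive). Default 0.05.
#' @param doublet_sd_multiplier Number of standard deviations above the mean
#'   that marks a lipid abundance as doublet-like. Default 2.5.
#' @param doublet_lipid_frac Fraction of a sample's detected lipids that must
#'   be doublet-like for the sample to be excluded as a doublet. Default 0.8.
#' @param marker_lipids Lipids whose complete absence marks a failed well
#'   (the extraction missed the cell). Default `c("PC 34:1", "PC 36:2")`,
#'   the two most abundant membrane phosphatidylcholines.
#' @param noise_window_da Half-width (Da) of the local window used to
#'   estimate spectral noise around a matched peak. Default 0.5, i.e. the
#'   same nominal-mass channel, so that genuine lipid signals at adjacent
#'   nominal masses are not counted as noise.
#' @param doublet_reference Population used for the doublet mean/SD:
#'   `"plate"` (default; raw intensities carry plate batch effects, so
#'   cross-plate pooling would inflate the SD) or `"global"`.
#'
#' @return An object of class `qc_thresholds` (a named list).
#' @examples
#' qc_thresholds()
#' qc_thresholds(ppm_max = 5)
#' @export
qc_thresholds <- function(ppm_max = 10,
                          snr_min = 1.5,
                          curve_r_min = 0.5,
                          presence_min_frac = 0.05,
                          doublet_sd_multiplier = 2.5,
                          doublet_lipid_frac = 0.8,
                          marker_lipids = c("PC 34:1", "PC 36:2"),
                          noise_window_da = 0.5,
                          doublet_reference = c("plate", "global")) {
  assert_scalar_number(ppm_max, "ppm_max", lower = .Machine$double.eps)
  assert_scalar_number(snr_min, "snr_min", lower = .Machine$double.eps)
  assert_scalar_number(curve_r_min, "curve_r_min", lower = .Machine$double.eps)
  assert_scalar_number(presence_min_frac, "presence_min_frac",
                       lower = .Machine$double.eps, upper = 1)
  assert_scalar_number(doublet_sd_multiplier, "doublet_sd_multiplier",
                       lower = .Machine$double.eps)
  assert_scalar_number(doublet_lipid_frac, "doublet_lipid_frac",
                       lower = .Machine$double.eps, upper = 1)
  assert_scalar_number(noise_window_da, "noise_window_da",
                       lower = .Machine$double.eps)
  if (!is.character(marker_lipids) || length(marker_lipids) < 1L) {
    stop_sclipid("'marker_lipids' must be a non-empty character vector",
                 class = "sclipid_config_error")
  }
  structure(list(
    ppm_max = ppm_max,
    snr_min = snr_min,
    curve_r_min = curve_r_min,
    presence_min_frac = presence_min_frac,
    doublet_sd_multiplier = doublet_sd_multiplier,
    doublet_lipid_frac = doublet_lipid_frac,
    marker_lipids = marker_lipids,
    noise_window_da = noise_window_da,
    doublet_reference = match.arg(doublet_reference)
  ), class = "qc_thresholds")
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat("QC thresholds:\n")
  cat(sprintf("  mass accuracy     <= %g ppm\n", x$ppm_max))
  cat(sprintf("  signal-to-noise    > %g\n", x$snr_min))
  cat(sprintf("  standard-curve r   > %g\n", x$curve_r_min))
  cat(sprintf("  presence fraction >= %g%%\n", 100 * x$presence_min_frac))
  cat(sprintf("  doublet rule: >= %g%% of detected lipids > mean + %g SD (%s reference)\n",
              100 * x$doublet_lipid_frac, x$doublet_sd_multiplier,
              x$doublet_reference))
  cat(sprintf("  failed-well markers: %s\n", paste(x$marker_lipids, collapse = ", ")))
  invisible(x)
}
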