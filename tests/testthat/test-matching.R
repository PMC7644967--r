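test_that("closest peak matches hand arithmetic", {
  sp <- spectrum("s", 760.5851, 100)
  hit <- closest_peak(sp, 760.5851, 10)
  expect_equal(hit$deviation_ppm, 0)
  expect_equal(hit$intensity, 100)

  sp2 <- spectrum("s", 760.5889, 50)
  hit2 <- closest_peak(sp2, 760.5851, 10)
  # 0.0038 / 760.5851 x 1e6 ~ 5.00 ppm
  expect_equal(hit2$deviation_ppm, 0.0038 / 760.5851 * 1e6, tolerance = 1e-9)
  expect_equal(round(hit2$deviation_ppm, 2), 5.00)

  expect_null(closest_peak(spectrum("e"), 760.5851, 10))
  expect_null(closest_peak(spectrum("s", 700, 10), 760.5851, 10))
})

test_that("ties at equal distance go to higher intensity, then lower m/z", {
  sp <- spectrum("s", c(759.9, 760.1), c(5, 50))
  expect_equal(closest_peak(sp, 760.0, 1000)$mz, 760.1)
  sp2 <- spectrum("s", c(759.9, 760.1), c(50, 50))
  expect_equal(closest_peak(sp2, 760.0, 1000)$mz, 759.9)
})

test_that("bracketed search equals exhaustive linear scan on random spectra", {
  set.seed(101)
  for (i in 1:1000) {
    sp <- random_spectrum("r", n = sample(c(1, 5, 200), 1))
    target <- runif(1, 640, 910)
    window <- sample(c(5, 50, 5000, Inf), 1)
    got <- closest_peak(sp, target, window)
    want <- brute_closest(sp, target, window)
    expect_identical(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_equal(got$mz, want$mz)
      expect_equal(got$intensity, want$intensity)
    }
  }
})

test_that("ppm deviation is invariant under uniform m/z scaling", {
  set.seed(7)
  sp <- random_spectrum("r", n = 50)
  target <- 750
  base <- closest_peak(sp, target, Inf)$deviation_ppm
  for (s in c(0.5, 2, 10)) {
    scaled <- spectrum("r", sp$peaks$mz * s, sp$peaks$intensity)
    expect_equal(closest_peak(scaled, target * s, Inf)$deviation_ppm, base,
                 tolerance = 1e-9)
  }
})

test_that("signal-to-noise boundary and fallback chain behave as specified", {
  # five neighbours at 100 around a 150 peak: snr exactly 1.5, fails > 1.5
  sp <- spectrum("s", c(760.2, 760.3, 760.4, 760.5, 760.6, 760.7),
                 c(100, 100, 150, 100, 100, 100))
  peak <- list(mz = 760.4, intensity = 150)
  expect_equal(estimate_snr(sp, peak, noise_window_da = 0.5), 1.5)
  th <- qc_thresholds()
  expect_false(estimate_snr(sp, peak, 0.5) > th$snr_min)

  # lone peak: no neighbours, no other peaks, snr = +Inf
  lone <- spectrum("s", 760.4, 10)
  expect_identical(estimate_snr(lone, list(mz = 760.4, intensity = 10), 0.5),
                   Inf)

  # no neighbours in window: falls back to 5th percentile of intensities
  far <- spectrum("s", c(700, 760.4, 820), c(4, 100, 4))
  expect_equal(estimate_snr(far, list(mz = 760.4, intensity = 100), 0.5),
               100 / quantile(c(4, 100, 4), 0.05, names = FALSE))

  expect_error(estimate_snr(lone, list(mz = 1, intensity = 1), 0.5),
               "not part of")
})

test_that("snr rises with configured signal scale at fixed noise", {
  snrs <- vapply(c(1, 4, 16), function(scale) {
    cfg <- simulation_config(n_plates = 1, wells_per_plate = 12,
                             base_scale = 2000 * scale, blank_fraction = 0,
                             failed_fraction = 0, doublet_fraction = 0,
                             qc_per_plate = 0, seed = 17)
    sim <- simulate_experiment(cfg)
    m <- match_all(sim$spectra, cfg$lipid_panel)
    median(m$matches$snr[m$matches$detected], na.rm = TRUE)
  }, 0)
  expect_true(all(diff(snrs) > 0))
})

test_that("match_all detection flags equal the brute-force definition", {
  cfg <- small_config(seed = 23)
  sim <- simulate_experiment(cfg)
  th <- qc_thresholds()
  m <- match_all(sim$spectra, cfg$lipid_panel, th)
  # every detected match satisfies both detection predicates
  det <- m$matches[m$matches$detected, ]
  expect_true(all(det$deviation_ppm <= th$ppm_max))
  expect_true(all(det$snr > th$snr_min))
  # spot-check full recomputation on a subset of spectra
  by_id <- setNames(sim$spectra, vapply(sim$spectra, `[[`, "", "sample_id"))
  set.seed(1)
  for (sid in sample(names(by_id), 10)) {
    sp <- by_id[[sid]]
    rows <- m$matches[m$matches$sample_id == sid, ]
    for (j in seq_len(nrow(cfg$lipid_panel))) {
      want <- brute_closest(sp, cfg$lipid_panel$target_mz[j], th$ppm_max)
      row <- rows[rows$lipid_name == cfg$lipid_panel$name[j], ]
      if (is.null(want)) {
        expect_false(row$detected)
        expect_identical(row$deviation_ppm, Inf)
      } else {
        snr <- estimate_snr(sp, want, th$noise_window_da)
        expect_equal(row$detected,
                     want$deviation_ppm <= th$ppm_max && snr > th$snr_min)
      }
    }
  }
  # raw matrix holds intensities exactly where detected
  for (sid in sample(names(by_id), 5)) {
    rows <- m$matches[m$matches$sample_id == sid, ]
    vals <- m$raw$values[sid, rows$lipid_name]
    expect_identical(unname(is.na(vals)), !rows$detected)
    expect_equal(unname(vals[rows$detected]), rows$intensity[rows$detected])
  }
})

test_that("blank assessment summarises global closest-signal deviations", {
  targets <- lipid_panel("PC 34:1")
  t_mz <- targets$target_mz
  mk <- function(ppm) spectrum(paste0("b", ppm), t_mz * (1 + ppm / 1e6), 1)
  out <- blank_assessment(list(mk(20), mk(40)), targets, ppm_max = 10)
  expect_equal(out$mean_closest_deviation_ppm, 30, tolerance = 1e-6)
  expect_equal(out$min_deviation_ppm, 20, tolerance = 1e-6)
  expect_equal(out$n_within_ppm_max, 0L)
  expect_equal(out$n_blanks, 2L)

  # a blank with no peaks is excluded from the mean and counted
  out2 <- blank_assessment(list(mk(20), mk(40), spectrum("empty")), targets)
  expect_equal(out2$mean_closest_deviation_ppm, 30, tolerance = 1e-6)
  expect_equal(out2$n_non_evaluable, 1L)
  expect_equal(out2$n_blanks, 3L)

  expect_error(blank_assessment(list(), targets), "at least one")
})

test_that("blank hits within the ppm window track the noise density", {
  targets <- default_panel()[1:2, ]
  count_hits <- function(density, seed) {
    cfg <- simulation_config(n_plates = 1, wells_per_plate = 40,
                             blank_fraction = 1, qc_per_plate = 0,
                             noise_peak_density = density, seed = seed)
    sim <- simulate_experiment(cfg)
    out <- blank_assessment(sim$spectra, targets, ppm_max = 10)
    # brute-force recount straight from the peak lists
    manual <- sum(vapply(sim$spectra, function(sp) {
      sum(vapply(seq_len(nrow(targets)), function(j) {
        w <- brute_closest(sp, targets$target_mz[j], Inf)
        !is.null(w) && w$deviation_ppm <= 10
      }, TRUE))
    }, 0))
    expect_equal(sum(out$n_within_ppm_max), manual)
    sum(out$n_within_ppm_max)
  }
  expect_lte(count_hits(0.2, 41), count_hits(50, 41))
})
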