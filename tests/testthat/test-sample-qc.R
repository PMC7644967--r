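make_samples <- function(ids, type = "single_cell", plate = 1L) {
  data.frame(sample_id = ids, sample_type = type, plate = plate,
             well = sprintf("W%02d", seq_along(ids)),
             injection_order = seq_along(ids),
             genotype = ifelse(type == "single_cell", "WT", NA),
             replicate = ifelse(type == "single_cell", "R1", NA),
             experiment_id = "exp1", n_cells = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("a single detected marker is enough to pass the failed-well rule", {
  matches <- data.frame(
    sample_id = rep(c("a", "b", "c"), each = 2),
    lipid_name = rep(c("PC 34:1", "PC 36:2"), 3),
    detected = c(TRUE, FALSE,   # a: one marker -> pass
                 FALSE, FALSE,  # b: neither -> failed
                 TRUE, TRUE),   # c: both -> pass
    stringsAsFactors = FALSE
  )
  out <- detect_failed(matches, make_samples(c("a", "b", "c")))
  expect_equal(out$failed, c(FALSE, TRUE, FALSE))

  # marker absent from panel is a configuration error
  th <- qc_thresholds(marker_lipids = c("PC 34:1", "PC 99:9"))
  expect_error(detect_failed(matches, make_samples(c("a", "b", "c")), th),
               "PC 99:9")
})

test_that("wells with no peaks at all are failed; non-cell wells never are", {
  cfg <- simulation_config(n_plates = 1, wells_per_plate = 30,
                           failed_fraction = 0.3, noise_peak_density = 0,
                           seed = 12)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  out <- detect_failed(m$matches, sim$samples)
  # only single-cell wells are classified
  expect_setequal(out$sample_id,
                  sim$samples$sample_id[sim$samples$sample_type == "single_cell"])
  tw <- sim$truth$wells
  want <- tw$label[match(out$sample_id, tw$sample_id)] == "failed"
  expect_equal(out$failed, want)
})

test_that("recovered failure rate stays inside the binomial interval", {
  cfg <- simulation_config(n_plates = 6, wells_per_plate = 96,
                           failed_fraction = 0.2, doublet_fraction = 0,
                           blank_fraction = 0, qc_per_plate = 0, seed = 33)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  out <- detect_failed(m$matches, sim$samples)
  n <- nrow(out)  # > 500 cells
  expect_gt(n, 500L)
  p_hat <- mean(out$failed)
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("extreme and central samples get the obvious doublet verdicts", {
  set.seed(2)
  n <- 20
  v <- matrix(rnorm(n * 5, 100, 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), letters[1:5]))
  v["s01", ] <- 100  # at the population centre -> pass
  v["s02", ] <- v["s02", ] + 10 * 5 * 10  # every lipid ~10 SD high -> doublet
  raw <- abundance_matrix(v)
  out <- detect_doublets(raw, make_samples(rownames(v)))
  expect_false(out$doublet[out$sample_id == "s01"])
  expect_true(out$doublet[out$sample_id == "s02"])
})

test_that("doublet flags are invariant to a global intensity rescaling", {
  cfg <- small_config(seed = 14)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  fails <- detect_failed(m$matches, sim$samples)
  fid <- fails$sample_id[fails$failed]
  a <- detect_doublets(m$raw, sim$samples, failed_ids = fid)
  scaled <- abundance_matrix(m$raw$values * 7.3)
  b <- detect_doublets(scaled, sim$samples, failed_ids = fid)
  expect_identical(a$doublet, b$doublet)
})

test_that("raising the SD multiplier never flags more samples", {
  cfg <- small_config(seed = 15)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  fails <- detect_failed(m$matches, sim$samples)
  fid <- fails$sample_id[fails$failed]
  flagged <- lapply(c(1.5, 2.5, 4, 8), function(k) {
    th <- qc_thresholds(doublet_sd_multiplier = k)
    out <- detect_doublets(m$raw, sim$samples, th, failed_ids = fid)
    out$sample_id[out$doublet]
  })
  for (i in seq_len(length(flagged) - 1L)) {
    expect_true(all(flagged[[i + 1L]] %in% flagged[[i]]))
  }
})

test_that("doublet verdicts equal an explicit-loop recomputation", {
  cfg <- small_config(seed = 16)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  fails <- detect_failed(m$matches, sim$samples)
  fid <- fails$sample_id[fails$failed]
  out <- detect_doublets(m$raw, sim$samples, failed_ids = fid)
  keep <- sim$samples$sample_type == "single_cell" &
    !(sim$samples$sample_id %in% fid)
  v <- m$raw$values[sim$samples$sample_id[keep], , drop = FALSE]
  want <- brute_doublets(v, sim$samples$plate[keep], 2.5, 0.8)
  expect_identical(setNames(out$doublet, out$sample_id), want[out$sample_id])
})

test_that("small reference groups are not evaluable, never a silent pass", {
  v <- matrix(rnorm(8, 100, 5), 2, 4,
              dimnames = list(c("a", "b"), letters[1:4]))
  out <- detect_doublets(abundance_matrix(v), make_samples(c("a", "b")))
  expect_true(all(out$status == "not_evaluable"))
  expect_false(any(out$doublet))
})

test_that("simulation recovery: failed and doublet detection beat 0.9/0.9", {
  cfg <- simulation_config(seed = 20)  # documented defaults
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  qc <- sample_qc(m$matches, m$raw, sim$samples)
  tw <- sim$truth$wells
  tl <- tw$label[match(qc$sample_id, tw$sample_id)]
  expect_gt(mean(qc$status[tl == "failed"] == "failed_no_marker"), 0.9)
  expect_gt(mean(qc$status[tl != "failed"] != "failed_no_marker"), 0.9)
  expect_gt(mean(qc$status[tl == "doublet"] == "excluded_doublet"), 0.9)
  expect_gt(mean(qc$status[!(tl %in% c("failed", "doublet"))] !=
                   "excluded_doublet"), 0.9)
})

test_that("doublet detection refuses normalized input", {
  v <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("s", c("a", "b")))
  norm <- abundance_matrix(v, normalized = TRUE)
  expect_error(detect_doublets(norm, make_samples("s")), "un-normalized")
})
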