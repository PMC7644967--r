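cell_samples <- function(ids, genotype, replicate = "R1") {
  data.frame(sample_id = ids, sample_type = "single_cell", plate = 1L,
             well = ids, injection_order = seq_along(ids),
             genotype = genotype, replicate = replicate,
             experiment_id = "exp1", n_cells = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("population profiles are per-replicate means over detected values", {
  v <- rbind(c1 = c(0.2, 0.3), c2 = c(0.4, 0.5))
  colnames(v) <- c("a", "b")
  out <- population_profiles(abundance_matrix(v), cell_samples(c("c1", "c2"), "WT"))
  expect_equal(unname(out$profiles$values["WT.R1", ]), c(0.3, 0.4))
  expect_equal(out$n_cells[["WT.R1"]], 2L)

  # a lipid missing in every cell of the replicate stays missing
  v2 <- rbind(c1 = c(0.2, NA), c2 = c(0.4, NA))
  colnames(v2) <- c("a", "b")
  out2 <- population_profiles(abundance_matrix(v2),
                              cell_samples(c("c1", "c2"), "WT"))
  expect_true(is.na(out2$profiles$values["WT.R1", "b"]))
})

test_that("population contrasts recover the configured genotype direction", {
  cfg <- simulation_config(n_plates = 4, wells_per_plate = 48, seed = 44,
                           blank_fraction = 0, failed_fraction = 0,
                           doublet_fraction = 0, qc_per_plate = 0)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  norm <- total_signal_normalize(m$raw)
  pop <- population_profiles(norm, sim$samples)
  prof <- pop$profiles$values
  wt <- grepl("^WT\\.", rownames(prof))
  # the mutant deficit lipid is lower in every mutant replicate than in
  # every wild-type replicate
  expect_lt(max(prof[!wt, "PC 36:2"]), min(prof[wt, "PC 36:2"]))
})

test_that("identical groups give fold change 1 and p near 1", {
  y <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("WT", "MU"), each = 5)
  out <- group_test(y, g, reference = "WT")
  expect_equal(out$fold_change, 1)
  expect_gt(out$p_value, 0.99)
  expect_identical(out$status, "ok")
})

test_that("the linear-model p equals the equal-variance t-test closed form", {
  set.seed(91)
  for (i in 1:50) {
    y <- exp(rnorm(24, 0, 0.4))
    g <- rep(c("a", "b"), each = 12)
    got <- group_test(y, g, reference = "a")
    want <- t.test(log(y[g == "b"]), log(y[g == "a"]), var.equal = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
    expect_equal(got$fold_change, mean(y[g == "b"]) / mean(y[g == "a"]))
  }
})

test_that("degenerate group inputs are not evaluable, never NaN", {
  out <- group_test(c(1, 2, 3), c("a", "a", "a"))
  expect_identical(out$status, "not_evaluable")
  expect_true(is.na(out$p_value) && !is.nan(out$p_value))
  out2 <- group_test(c(1, 2, 1, 2), c("a", "a", "b", "b"))  # n < 3 per group
  expect_identical(out2$status, "not_evaluable")
})

test_that("null p-values are uniform: KS test and type-I rate", {
  set.seed(18)
  p <- replicate(1000, {
    y <- exp(rnorm(40, 0, 0.3))
    g <- rep(c("a", "b"), each = 20)
    group_test(y, g)$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("median split sends ties low and flags degenerate strata", {
  ids <- c("c1", "c2", "c3", "c4")
  v <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(ids, "PC 36:2"))
  coh <- stratify_by_lipid(abundance_matrix(v), cell_samples(ids, "WT"))
  expect_equal(setNames(coh$stratum, coh$sample_id),
               c(c1 = "low", c2 = "low", c3 = "high", c4 = "high"))

  v2 <- matrix(5, 4, 1, dimnames = list(ids, "PC 36:2"))
  coh2 <- stratify_by_lipid(abundance_matrix(v2), cell_samples(ids, "WT"))
  expect_true(all(coh2$stratum == "low"))
  expect_true(attr(coh2, "degenerate"))

  # cells missing the lipid are unassigned; too few assignable errors out
  v3 <- matrix(c(1, 2, NA, NA), 4, 1, dimnames = list(ids, "PC 36:2"))
  expect_error(stratify_by_lipid(abundance_matrix(v3),
                                 cell_samples(ids, "WT")), ">= 4")
})

test_that("strata recover the true mixture component of the bimodal lipid", {
  cfg <- simulation_config(seed = 3, bimodality_fraction = 0.5)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  qc <- sample_qc(m$matches, m$raw, sim$samples)
  cells <- passing_cells(qc)
  norm <- total_signal_normalize(subset_matrix(m$raw, samples = cells))
  coh <- stratify_by_lipid(norm, sim$samples, cells = cells)
  tw <- sim$truth$wells
  mut <- coh[coh$genotype == "A53T", ]
  truth_low <- tw$bimodal_low[match(mut$sample_id, tw$sample_id)]
  expect_gt(mean((mut$stratum == "low") == truth_low, na.rm = TRUE), 0.9)
})

test_that("stratified fold changes equal the direct mean ratio and keep sign", {
  set.seed(5)
  ids <- sprintf("c%02d", 1:40)
  v <- cbind("PC 36:2" = rlnorm(40, 0, 0.5),
             "PC 34:1" = rlnorm(40, 0, 0.3),
             "PE 36:2" = rlnorm(40, 0, 0.3))
  rownames(v) <- ids
  # couple PC 34:1 negatively to PC 36:2 (lower when PC 36:2 is high)
  v[, "PC 34:1"] <- v[, "PC 34:1"] / (1 + v[, "PC 36:2"])
  mat <- abundance_matrix(v)
  coh <- stratify_by_lipid(mat, cell_samples(ids, "WT"))
  st <- stratified_tests(mat, coh, targets = lipid_panel(colnames(v)))
  hi <- coh$sample_id[coh$stratum == "high"]
  lo <- coh$sample_id[coh$stratum == "low"]
  for (lip in colnames(v)) {
    row <- st[st$variable == lip, ]
    expect_equal(row$fold_change, mean(v[hi, lip]) / mean(v[lo, lip]),
                 tolerance = 1e-12)
  }
  # the negatively coupled lipid has FC < 1 relative to the low stratum
  expect_lt(st$fold_change[st$variable == "PC 34:1"], 1)
  expect_gt(st$fold_change[st$variable == "PC 36:2"], 1)
  # PC/PE row is present and equals the mean ratio contrast
  ratio <- pc_pe_ratio(mat, lipid_panel(colnames(v)))
  row <- st[st$variable == "PC/PE", ]
  expect_equal(row$fold_change, mean(ratio[hi]) / mean(ratio[lo]),
               tolerance = 1e-12)
})

test_that("PC/PE ratio sums detected class members and is normalization invariant", {
  targets <- lipid_panel(c("PC 34:1", "PC 36:2", "PE 36:1", "PE 36:2"))
  v <- matrix(c(0.3, 0.3, 0.2, 0.1,
                0.4, 0.2, NA, NA), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), targets$name))
  m <- abundance_matrix(v)
  r <- pc_pe_ratio(m, targets)
  expect_equal(unname(r["s1"]), 2.0)
  expect_true(is.na(r[["s2"]]))  # no detected PE

  raw <- abundance_matrix(v * c(13, 1))
  expect_equal(pc_pe_ratio(total_signal_normalize(
    abundance_matrix(v[1, , drop = FALSE])), targets)[["s1"]],
    r[["s1"]], tolerance = 1e-12)
})

test_that("between-replicate spread of population means never exceeds cell spread", {
  cfg <- simulation_config(n_plates = 3, wells_per_plate = 64, seed = 50,
                           blank_fraction = 0, failed_fraction = 0,
                           doublet_fraction = 0, qc_per_plate = 0)
  sim <- simulate_experiment(cfg)
  m <- match_all(sim$spectra, cfg$lipid_panel)
  norm <- total_signal_normalize(m$raw)
  wt <- sim$samples[sim$samples$genotype == "WT", ]
  pop <- population_profiles(norm, wt)
  for (lip in c("PC 34:1", "PC 36:2", "PE 34:1")) {
    sd_rep <- sd(pop$profiles$values[, lip], na.rm = TRUE)
    sd_cell <- sd(norm$values[wt$sample_id, lip], na.rm = TRUE)
    expect_lte(sd_rep, sd_cell)
  }
})
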