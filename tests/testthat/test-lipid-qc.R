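test_that("presence fractions, including the inclusive 5% boundary", {
  v <- matrix(NA_real_, 96, 2, dimnames = list(sprintf("c%02d", 1:96),
                                               c("a", "b")))
  v[1:9, 1] <- 1       # 9 of 96
  v[1:4, 2] <- 1       # 4 of 96 = 4.17%
  m <- abundance_matrix(v)
  pres <- presence_fraction(m, rownames(v))
  expect_equal(unname(pres["b"]), 4 / 96)
  expect_lt(pres[["b"]], 0.05)

  v2 <- matrix(NA_real_, 10, 1, dimnames = list(sprintf("c%d", 1:10), "a"))
  v2[1:9, 1] <- 1
  expect_equal(unname(presence_fraction(abundance_matrix(v2),
                                        rownames(v2))), 0.9)

  # exactly 5% passes the inclusive threshold
  v3 <- matrix(NA_real_, 40, 1, dimnames = list(sprintf("c%d", 1:40), "a"))
  v3[1:2, 1] <- 1  # 2/40 = 5.0%
  p <- presence_fraction(abundance_matrix(v3), rownames(v3))
  expect_true(p[["a"]] >= qc_thresholds()$presence_min_frac)

  expect_error(presence_fraction(m, character()), "non-empty")
})

test_that("curve linearity handles exact, noisy-null and degenerate cases", {
  counts <- c(1, 2, 5, 10, 20)
  v <- matrix(counts * 3.7, 5, 1, dimnames = list(sprintf("w%d", 1:5), "a"))
  r <- curve_linearity(abundance_matrix(v), counts)
  expect_equal(unname(r["a"]), 1)

  # intensities independent of counts rarely reach r > 0.5
  set.seed(77)
  hits <- replicate(200, {
    y <- matrix(rexp(5, 1), 5, 1, dimnames = list(sprintf("w%d", 1:5), "a"))
    unname(curve_linearity(abundance_matrix(y), counts)["a"]) > 0.5
  })
  expect_lt(mean(hits), 0.25)

  v2 <- matrix(c(1, 2, NA, NA, NA), 5, 1,
               dimnames = list(sprintf("w%d", 1:5), "a"))
  expect_true(is.na(curve_linearity(abundance_matrix(v2), counts)["a"]))

  v3 <- matrix(5, 5, 1, dimnames = list(sprintf("w%d", 1:5), "a"))
  expect_true(is.na(curve_linearity(abundance_matrix(v3), counts)["a"]))
})

test_that("the four filters pass a clean simulated panel and match recomputation", {
  cfg <- simulation_config(n_plates = 2, wells_per_plate = 48, seed = 19)
  sim <- simulate_study(cfg)
  th <- qc_thresholds()
  m <- match_all(sim$spectra, cfg$lipid_panel, th)
  qc <- sample_qc(m$matches, m$raw, sim$samples, th)
  cells <- passing_cells(qc)
  rep1 <- apply_filters(m$matches, m$raw, sim$samples, cells, th)
  expect_true(all(rep1$passes))

  # independent recomputation of the four predicates
  pres <- presence_fraction(m$raw, cells)
  cw <- sim$samples[sim$samples$sample_type == "curve_standard", ]
  r <- curve_linearity(subset_matrix(m$raw, samples = cw$sample_id),
                       cw$n_cells)
  det <- m$matches[m$matches$detected & m$matches$sample_id %in% cells, ]
  for (i in seq_len(nrow(rep1))) {
    lip <- rep1$lipid_name[i]
    sub <- det[det$lipid_name == lip, ]
    expect_equal(rep1$within_ppm[i], median(sub$deviation_ppm) <= th$ppm_max)
    expect_equal(rep1$snr_pass[i], median(sub$snr) > th$snr_min)
    expect_equal(rep1$curve_pass[i],
                 !is.na(r[[lip]]) && r[[lip]] > th$curve_r_min)
    expect_equal(rep1$presence_pass[i], pres[[lip]] >= th$presence_min_frac)
    expect_equal(rep1$passes[i],
                 rep1$within_ppm[i] && rep1$snr_pass[i] &&
                   rep1$curve_pass[i] && rep1$presence_pass[i])
  }

  # a lipid absent from every spectrum has presence 0 and fails
  ghost <- lipid_panel("TG 52:2")
  m2 <- match_all(sim$spectra, rbind(cfg$lipid_panel, ghost), th)
  rep2 <- apply_filters(m2$matches, m2$raw, sim$samples, cells, th)
  row <- rep2[rep2$lipid_name == "TG 52:2", ]
  expect_equal(row$presence_frac, 0)
  expect_false(row$passes)
})

test_that("tier levels follow the pass-count definition", {
  mk <- function(lipid, exps, pass_in) {
    data.frame(lipid_name = lipid, experiment_id = exps,
               passes = exps %in% pass_in, stringsAsFactors = FALSE)
  }
  exps <- c("e1", "e2", "e3")
  reports <- rbind(mk("all three", exps, exps),
                   mk("one and three", exps, c("e1", "e3")),
                   mk("two only", exps, "e2"),
                   mk("never", exps, character()))
  tiers <- assign_tiers(reports)
  lev <- setNames(tiers$level, tiers$lipid_name)
  expect_equal(lev[["all three"]], 1L)
  expect_equal(lev[["one and three"]], 2L)
  expect_equal(lev[["two only"]], 3L)
  expect_false("never" %in% tiers$lipid_name)
  expect_equal(attr(tiers, "n_dropped"), 1L)
  # partition identity
  expect_equal(nrow(tiers), sum(table(tiers$level)))
})

test_that("the digitized presence table yields 37 level-1 lipids (25 PC, 9 PE, 3 SM)", {
  pres <- presence_matrix()
  tiers <- tiers_from_presence(pres, min_pct = 5)
  expect_equal(sum(tiers$level == 1L), 37L)
  panel <- default_panel()
  cls <- table(panel$lipid_class[match(tiers$lipid_name[tiers$level == 1L],
                                       panel$name)])
  expect_equal(cls[["PC"]], 25L)
  expect_equal(cls[["PE"]], 9L)
  expect_equal(cls[["SM"]], 3L)
})

test_that("lowering the presence threshold never demotes a tier", {
  set.seed(55)
  pres <- matrix(runif(60, 0, 30), 20, 3,
                 dimnames = list(sprintf("L%02d", 1:20), c("e1", "e2", "e3")))
  t_strict <- tiers_from_presence(pres, min_pct = 10)
  t_loose <- tiers_from_presence(pres, min_pct = 2)
  common <- intersect(t_strict$lipid_name, t_loose$lipid_name)
  ls <- setNames(t_strict$level, t_strict$lipid_name)[common]
  ll <- setNames(t_loose$level, t_loose$lipid_name)[common]
  expect_true(all(ll <= ls))
  expect_true(all(t_strict$lipid_name %in% t_loose$lipid_name))
})
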