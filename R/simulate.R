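#' Configuration of the synthetic single-cell lipid experiment
#'
#' The generator emulates the statistical structure of a FACS-dispensed
#' single-cell LESA-MS study: plates of wells holding one cell (or,
#' erroneously, none or two), extraction blanks, pooled QC wells on every
#' plate, multiplicative plate batch effects, per-cell size variation,
#' ppm-scale mass jitter, chemical background peaks, and a genotype with a
#' partly bimodal lipid deficit. The defaults describe a study of seven
#' 96-well plates per experiment, two genotypes with four biological
#' replicates each, and the 37-lipid default panel.
#'
#' The per-well model for a single-cell well \eqn{i}, lipid \eqn{\ell} is
#' \deqn{I_{i\ell} = b_\ell \; s_i \; p_{plate(i)} \; g_{\ell}(geno_i) \;
#'   e^{\epsilon_{i\ell}}}
#' with \eqn{b_\ell} the base abundance, \eqn{s_i} a lognormal cell-size
#' factor with mean 1 and CV `cell_size_cv` (doublets draw \eqn{s_i} from
#' twice that distribution), \eqn{p} a lognormal plate batch factor,
#' \eqn{g} the genotype effect, and \eqn{\epsilon \sim N(0,
#' \sigma^2_{noise})} lognormal measurement noise. Peak m/z values are the
#' target m/z perturbed by `Normal(0, ppm_jitter_sd)` ppm; peaks below
#' `llod` are not recorded (they become missing values downstream); blanks
#' contain only background peaks; failed wells (the extraction missed the
#' cell) omit both marker lipids.
#'
#' @param n_plates Plates per experiment. Default 7.
#' @param wells_per_plate Wells per plate. Default 96.
#' @param n_experiments Independent experiments to generate. Default 1.
#' @param lipid_panel Target panel data frame (see [lipid_panel()]).
#' @param base_abundance Named positive vector of per-lipid per-cell base
#'   intensities. Default: a geometric abundance ladder over the panel
#'   spanning `abundance_distribution_shape` decades, with the marker
#'   lipids placed at the top (they are the most abundant species).
#' @param abundance_distribution_shape Decades spanned by the default
#'   abundance ladder (the lipid abundance distribution is strongly
#'   non-linear). Default 2.
#' @param base_scale Intensity of the most abundant lipid. Default 2000.
#' @param cell_size_cv Coefficient of variation of the per-cell size
#'   factor. Default 0.05 (FACS gating on a narrow size window dispenses
#'   cells of tightly similar lipid content).
#' @param ppm_jitter_sd SD of the mass error in ppm. Default 2.
#' @param noise_peak_density Background peaks per Da. Default 0.5.
#' @param noise_intensity_scale Mean of the exponential background peak
#'   intensity. Default 1.
#' @param lognormal_noise_sd SD (log scale) of multiplicative per-peak
#'   measurement noise. Default 0.05.
#' @param blank_fraction Fraction of wells that are extraction blanks.
#'   Default 0.1.
#' @param failed_fraction Fraction of cell wells where the extraction
#'   missed the cell. Default 0.05.
#' @param doublet_fraction Fraction of cell wells holding two cells.
#'   Default 0.05.
#' @param plate_batch_effect_sd SD (log scale) of the multiplicative plate
#'   factor. Default 0.3.
#' @param genotype_effect Named vector of multiplicative shifts applied to
#'   the second genotype. Default: reduced PC 36:2, PC 36:1, PC 34:2 and
#'   PC 32:0, the species with genotype differences.
#' @param bimodal_lipid The lipid whose mutant deficit is a two-component
#'   mixture rather than a uniform shift. Default `"PC 36:2"`.
#' @param bimodality_fraction Fraction of mutant cells drawn from the low
#'   mode of `bimodal_lipid`. Default 0.6.
#' @param genotypes Group labels; the second receives `genotype_effect`.
#' @param n_replicates Biological replicates per genotype. Default 4.
#' @param qc_per_plate Pooled-QC wells per plate. Default 6.
#' @param qc_scale Material in a pooled QC relative to one cell. Default 10.
#' @param llod Lower limit of detection (intensity). Default 5.
#' @param mz_range m/z range of the background. Default: panel range +- 50 Da.
#' @param seed Integer seed; a fixed seed makes all outputs bit-reproducible.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_plates = 7,
                              wells_per_plate = 96,
                              n_experiments = 1,
                              lipid_panel = default_panel(),
                              base_abundance = NULL,
                              abundance_distribution_shape = 2,
                              base_scale = 2000,
                              cell_size_cv = 0.05,
                              ppm_jitter_sd = 2,
                              noise_peak_density = 0.5,
                              noise_intensity_scale = 1,
                              lognormal_noise_sd = 0.05,
                              blank_fraction = 0.1,
                              failed_fraction = 0.05,
                              doublet_fraction = 0.05,
                              plate_batch_effect_sd = 0.3,
                              genotype_effect = c("PC 36:2" = 0.5,
                                                  "PC 36:1" = 0.7,
                                                  "PC 34:2" = 0.75,
                                                  "PC 32:0" = 0.8),
                              bimodal_lipid = "PC 36:2",
                              bimodality_fraction = 0.6,
                              genotypes = c("WT", "A53T"),
                              n_replicates = 4,
                              qc_per_plate = 6,
                              qc_scale = 10,
                              llod = 5,
                              mz_range = NULL,
                              seed = 1L) {
  if (!is.numeric(n_plates) || n_plates < 1 ||
      !is.numeric(wells_per_plate) || wells_per_plate < 1) {
    stop_sclipid("n_plates and wells_per_plate must be positive integers",
                 class = "sclipid_config_error")
  }
  if (!is.data.frame(lipid_panel) || nrow(lipid_panel) == 0L) {
    stop_sclipid("lipid_panel must be a non-empty target panel",
                 class = "sclipid_config_error")
  }
  lipid_panel <- .validate_targets(lipid_panel)
  for (f in c("blank_fraction", "failed_fraction", "doublet_fraction",
              "bimodality_fraction")) {
    assert_scalar_number(get(f), f, lower = 0, upper = 1)
  }
  assert_scalar_number(cell_size_cv, "cell_size_cv", lower = 0)
  assert_scalar_number(ppm_jitter_sd, "ppm_jitter_sd", lower = 0)
  assert_scalar_number(noise_peak_density, "noise_peak_density", lower = 0)
  assert_scalar_number(noise_intensity_scale, "noise_intensity_scale",
                       lower = 0)
  assert_scalar_number(plate_batch_effect_sd, "plate_batch_effect_sd",
                       lower = 0)
  assert_scalar_number(llod, "llod", lower = 0)

  if (is.null(base_abundance)) {
    nms <- lipid_panel$name
    markers <- intersect(c("PC 34:1", "PC 36:2"), nms)
    ord <- c(markers, setdiff(nms, markers))
    n <- length(ord)
    expo <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0
    base_abundance <- stats::setNames(
      base_scale * 10^(-abundance_distribution_shape * expo), ord)[nms]
  }
  if (is.null(names(base_abundance)) ||
      !setequal(names(base_abundance), lipid_panel$name)) {
    stop_sclipid("base_abundance must be named for every panel lipid",
                 class = "sclipid_config_error")
  }
  if (any(base_abundance <= 0)) {
    stop_sclipid("base abundances must be strictly positive",
                 class = "sclipid_config_error")
  }
  if (is.null(mz_range)) {
    mz_range <- c(floor(min(lipid_panel$target_mz)) - 50,
                  ceiling(max(lipid_panel$target_mz)) + 50)
  }
  if (length(genotypes) < 1L) {
    stop_sclipid("at least one genotype required",
                 class = "sclipid_config_error")
  }
  structure(list(
    n_plates = as.integer(n_plates),
    wells_per_plate = as.integer(wells_per_plate),
    n_experiments = as.integer(n_experiments),
    lipid_panel = lipid_panel,
    base_abundance = base_abundance[lipid_panel$name],
    abundance_distribution_shape = abundance_distribution_shape,
    cell_size_cv = cell_size_cv,
    ppm_jitter_sd = ppm_jitter_sd,
    noise_peak_density = noise_peak_density,
    noise_intensity_scale = noise_intensity_scale,
    lognormal_noise_sd = lognormal_noise_sd,
    blank_fraction = blank_fraction,
    failed_fraction = failed_fraction,
    doublet_fraction = doublet_fraction,
    plate_batch_effect_sd = plate_batch_effect_sd,
    genotype_effect = genotype_effect,
    bimodal_lipid = bimodal_lipid,
    bimodality_fraction = bimodality_fraction,
    genotypes = genotypes,
    n_replicates = as.integer(n_replicates),
    qc_per_plate = as.integer(qc_per_plate),
    qc_scale = qc_scale,
    llod = llod,
    mz_range = mz_range,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# lognormal with mean 1 and the requested coefficient of variation
.rsize <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.well_names <- function(n_wells) {
  rows <- LETTERS[1:8]
  cols <- sprintf("%02d", 1:12)
  grid <- as.vector(t(outer(rows, cols, paste0)))
  if (n_wells <= length(grid)) grid[seq_len(n_wells)]
  else sprintf("W%03d", seq_len(n_wells))
}

.noise_peaks <- function(config) {
  width <- diff(config$mz_range)
  k <- stats::rpois(1L, config$noise_peak_density * width)
  if (k == 0L) return(list(mz = numeric(), intensity = numeric()))
  list(mz = stats::runif(k, config$mz_range[1L], config$mz_range[2L]),
       intensity = stats::rexp(k, rate = 1 / config$noise_intensity_scale))
}

# assemble one spectrum from true lipid intensities + fresh background;
# lipids with intensity below the LLOD (or dropped names) yield no peak
.build_spectrum <- function(sample_id, config, true_abund, drop_lipids = NULL) {
  panel <- config$lipid_panel
  keep <- !is.na(true_abund) & true_abund >= config$llod &
    !(panel$name %in% drop_lipids)
  mz <- panel$target_mz[keep] *
    (1 + stats::rnorm(sum(keep), 0, config$ppm_jitter_sd) / 1e6)
  it <- true_abund[keep]
  bg <- .noise_peaks(config)
  spectrum(sample_id, c(mz, bg$mz), c(it, bg$intensity))
}

#' Simulate a full single-cell lipid profiling experiment
#'
#' Generates spectra, sample metadata and a ground-truth table for
#' `n_experiments` independent experiments under the model described in
#' [simulation_config()]. Wells per plate are allocated as: `qc_per_plate`
#' pooled QCs, a `blank_fraction` share of extraction blanks, and the rest
#' single-cell wells split evenly over genotype x replicate; among cell
#' wells, `failed_fraction` are failures (marker lipids missing) and
#' `doublet_fraction` of the remainder hold two cells.
#'
#' @param config A [simulation_config()].
#' @return A list with `spectra` (list of [spectrum()]), `samples`
#'   (metadata data frame, see \link{sample-table}) and `truth`: a list with
#'   `wells` (`sample_id`, `label` in clean/blank/failed/doublet/qc_pool,
#'   `size_factor`, `plate_factor`, `bimodal_low` — whether a mutant cell
#'   drew the low mode of the bimodal lipid) and `abundance`, the matrix of
#'   true pre-noise lipid abundances (NA for blanks).
#' @examples
#' sim <- simulate_experiment(simulation_config(n_plates = 1, seed = 7))
#' length(sim$spectra)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, .simulate_experiment_impl(config))
}

.simulate_experiment_impl <- function(config) {
  spectra <- list()
  samples <- list()
  truth_wells <- list()
  truth_ab <- list()
  for (e in seq_len(config$n_experiments)) {
    exp_id <- sprintf("exp%d", e)
    out <- .simulate_one_experiment(config, exp_id)
    spectra <- c(spectra, out$spectra)
    samples[[e]] <- out$samples
    truth_wells[[e]] <- out$truth$wells
    truth_ab[[e]] <- out$truth$abundance
  }
  samples <- do.call(rbind, samples)
  truth <- list(wells = do.call(rbind, truth_wells),
                abundance = do.call(rbind, truth_ab))
  rownames(samples) <- NULL
  rownames(truth$wells) <- NULL
  list(spectra = spectra, samples = validate_samples(samples), truth = truth)
}

.simulate_one_experiment <- function(config, exp_id) {
  panel <- config$lipid_panel
  nl <- nrow(panel)
  n_total <- config$n_plates * config$wells_per_plate
  wells <- .well_names(config$wells_per_plate)

  # well roles: per plate the first qc_per_plate wells are QCs; blanks and
  # cells are interleaved deterministically across the remaining wells
  plate <- rep(seq_len(config$n_plates), each = config$wells_per_plate)
  well <- rep(wells, config$n_plates)
  role <- rep("single_cell", n_total)
  for (p in seq_len(config$n_plates)) {
    idx <- which(plate == p)
    role[idx[seq_len(min(config$qc_per_plate, length(idx)))]] <- "qc_pool"
  }
  free <- which(role == "single_cell")
  n_blank <- round(config$blank_fraction * n_total)
  n_blank <- min(n_blank, length(free))
  if (n_blank > 0L) {
    # spread blanks evenly across plates/positions
    pick <- free[round(seq(1L, length(free), length.out = n_blank))]
    role[pick] <- "blank"
  }

  cells <- which(role == "single_cell")
  n_cells <- length(cells)
  geno <- rep(NA_character_, n_total)
  repl <- rep(NA_character_, n_total)
  combos <- expand.grid(replicate = sprintf("R%d", seq_len(config$n_replicates)),
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)
  assign <- combos[rep_len(seq_len(nrow(combos)), n_cells), ]
  geno[cells] <- assign$genotype
  repl[cells] <- assign$replicate

  label <- role
  is_failed <- stats::runif(n_total) < config$failed_fraction & role == "single_cell"
  is_doublet <- stats::runif(n_total) < config$doublet_fraction &
    role == "single_cell" & !is_failed
  label[role == "single_cell"] <- "clean"
  label[is_failed] <- "failed"
  label[is_doublet] <- "doublet"

  plate_factor_tab <- exp(stats::rnorm(config$n_plates, 0,
                                       config$plate_batch_effect_sd))
  size <- rep(NA_real_, n_total)
  size[role == "single_cell"] <- .rsize(sum(role == "single_cell"),
                                        config$cell_size_cv)
  size[is_doublet] <- 2 * .rsize(sum(is_doublet), config$cell_size_cv)
  size[role == "qc_pool"] <- config$qc_scale *
    exp(stats::rnorm(sum(role == "qc_pool"), 0, config$lognormal_noise_sd))

  second_geno <- if (length(config$genotypes) >= 2L) config$genotypes[2L] else NA

  sample_id <- sprintf("%s_p%d_%s", exp_id, plate, well)
  ab <- matrix(NA_real_, nrow = n_total, ncol = nl,
               dimnames = list(sample_id, panel$name))
  spectra <- vector("list", n_total)
  bimodal_low <- rep(NA, n_total)
  for (i in seq_len(n_total)) {
    if (role[i] == "blank") {
      bg <- .noise_peaks(config)
      spectra[[i]] <- spectrum(sample_id[i], bg$mz, bg$intensity)
      next
    }
    g <- rep(1, nl)
    if (role[i] == "single_cell" && identical(geno[i], second_geno)) {
      for (lip in names(config$genotype_effect)) {
        j <- match(lip, panel$name)
        if (is.na(j)) next
        if (identical(lip, config$bimodal_lipid)) {
          bimodal_low[i] <- stats::runif(1) < config$bimodality_fraction
          if (bimodal_low[i]) {
            g[j] <- config$genotype_effect[[lip]]
          }
        } else {
          g[j] <- config$genotype_effect[[lip]]
        }
      }
    }
    noise <- exp(stats::rnorm(nl, 0, config$lognormal_noise_sd))
    ab[i, ] <- config$base_abundance * size[i] * plate_factor_tab[plate[i]] *
      g * noise
    drop <- if (label[i] == "failed") .default_markers(config) else NULL
    spectra[[i]] <- .build_spectrum(sample_id[i], config, ab[i, ], drop)
  }

  samples <- data.frame(
    sample_id = sample_id,
    sample_type = role,
    plate = plate,
    well = well,
    injection_order = seq_len(n_total),
    genotype = geno,
    replicate = repl,
    experiment_id = exp_id,
    n_cells = NA_integer_,
    stringsAsFactors = FALSE
  )
  truth <- list(
    wells = data.frame(sample_id = sample_id, label = label,
                       size_factor = size,
                       plate_factor = plate_factor_tab[plate],
                       bimodal_low = bimodal_low,
                       stringsAsFactors = FALSE),
    abundance = ab
  )
  list(spectra = spectra, samples = samples, truth = truth)
}

.default_markers <- function(config) {
  intersect(c("PC 34:1", "PC 36:2"), config$lipid_panel$name)
}

#' Simulate cell standard-curve wells
#'
#' Wells containing a known number of cells, used to verify that lipid
#' signal scales linearly with the amount of biological material. Intensity
#' is exactly `n_cells x base_abundance` before multiplicative lognormal
#' noise; mass jitter, background peaks and the LLOD apply as for cell
#' wells. Repeat counts to obtain replicate wells.
#'
#' @param config A [simulation_config()].
#' @param cell_counts Integer vector, one well per element, each >= 1.
#' @param experiment_id Experiment label for the metadata. Default "exp1".
#' @param plate Plate number for the metadata. Default 1.
#' @param seed_offset Added to `config$seed` so curve randomness is
#'   independent of the main experiment draw. Default 1.
#' @return A list with `spectra` and `samples` (wells marked
#'   `curve_standard` with their `n_cells`).
#' @export
simulate_standard_curve <- function(config, cell_counts,
                                    experiment_id = "exp1", plate = 1L,
                                    seed_offset = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(cell_counts) == 0L) {
    stop_sclipid("cell_counts must be non-empty", class = "sclipid_config_error")
  }
  if (any(cell_counts < 1)) {
    stop_sclipid("all cell_counts must be >= 1", class = "sclipid_config_error")
  }
  with_seed(config$seed + seed_offset, {
    panel <- config$lipid_panel
    nl <- nrow(panel)
    n <- length(cell_counts)
    sample_id <- sprintf("%s_curve_%02d", experiment_id, seq_len(n))
    spectra <- vector("list", n)
    for (i in seq_len(n)) {
      noise <- exp(stats::rnorm(nl, 0, config$lognormal_noise_sd))
      ab <- cell_counts[i] * config$base_abundance * noise
      spectra[[i]] <- .build_spectrum(sample_id[i], config, ab)
    }
    samples <- data.frame(
      sample_id = sample_id,
      sample_type = "curve_standard",
      plate = as.integer(plate),
      well = sprintf("C%02d", seq_len(n)),
      injection_order = seq_len(n),
      genotype = NA_character_,
      replicate = NA_character_,
      experiment_id = experiment_id,
      n_cells = as.integer(cell_counts),
      stringsAsFactors = FALSE
    )
    list(spectra = spectra, samples = validate_samples(samples))
  })
}

#' Simulate experiments together with their standard curves
#'
#' Convenience wrapper running [simulate_experiment()] and one
#' [simulate_standard_curve()] per experiment (seed offset = experiment
#' index), merging metadata with globally consistent injection orders.
#'
#' @param config A [simulation_config()].
#' @param curve_cell_counts Cell counts of the curve wells added to each
#'   experiment. Default `rep(c(5, 10, 25, 50), 2)` (four levels in
#'   duplicate).
#' @return As [simulate_experiment()], with curve wells appended (curve
#'   wells have truth label `curve_standard` and no truth abundances).
#' @export
simulate_study <- function(config, curve_cell_counts = rep(c(5, 10, 25, 50), 2)) {
  sim <- simulate_experiment(config)
  exp_ids <- unique(sim$samples$experiment_id)
  for (e in seq_along(exp_ids)) {
    cur <- simulate_standard_curve(config, curve_cell_counts,
                                   experiment_id = exp_ids[e],
                                   plate = 1L, seed_offset = e)
    base_order <- max(sim$samples$injection_order[
      sim$samples$experiment_id == exp_ids[e]])
    cur$samples$injection_order <- base_order + cur$samples$injection_order
    sim$spectra <- c(sim$spectra, cur$spectra)
    sim$samples <- rbind(sim$samples, cur$samples)
    nl <- nrow(config$lipid_panel)
    ab <- matrix(NA_real_, nrow = nrow(cur$samples), ncol = nl,
                 dimnames = list(cur$samples$sample_id,
                                 config$lipid_panel$name))
    sim$truth$wells <- rbind(sim$truth$wells,
                             data.frame(sample_id = cur$samples$sample_id,
                                        label = "curve_standard",
                                        size_factor = NA_real_,
                                        plate_factor = NA_real_,
                                        bimodal_low = NA,
                                        stringsAsFactors = FALSE))
    sim$truth$abundance <- rbind(sim$truth$abundance, ab)
  }
  sim$samples <- validate_samples(sim$samples)
  sim
}
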