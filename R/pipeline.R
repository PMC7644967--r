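#' @title Pipeline orchestration
#' @description One call (or one shell command via the `sclipid` script in
#'   `exec/`) running the full chain: match -> sample QC -> lipid QC ->
#'   normalize -> tiers -> stats, writing every stage output as CSV plus a
#'   JSON provenance manifest with thresholds, seed and per-stage counts.
#' @name pipeline
NULL

.pipeline_stages <- c("match", "sample_qc", "lipid_qc", "normalize",
                      "tiers", "stats")

#' Pipeline run configuration
#'
#' @param spectra Path to spectra (directory of peak-list CSVs, a combined
#'   CSV, or an mzML file) or a list of [spectrum()] objects.
#' @param targets Path to a target CSV or a target panel data frame.
#' @param samples Path to a sample metadata CSV or a data frame.
#' @param out_dir Output directory (created if needed).
#' @param thresholds A [qc_thresholds()].
#' @param stages Stages to run; must be a prefix of
#'   `match, sample_qc, lipid_qc, normalize, tiers, stats`.
#' @param stratify_lipid Lipid used for stratified statistics.
#'   Default `"PC 36:2"`.
#' @param spectra_format Format passed to [read_spectra()] when `spectra`
#'   is a path.
#' @param seed Seed for the permutation tests in the stats stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spectra, targets, samples, out_dir,
                       thresholds = qc_thresholds(),
                       stages = .pipeline_stages,
                       stratify_lipid = "PC 36:2",
                       spectra_format = c("peaklist_csv", "mzml"),
                       seed = 1L) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  if (!identical(stages, .pipeline_stages[seq_along(stages)])) {
    stop_sclipid("stages must be a prefix of: %s",
                 paste(.pipeline_stages, collapse = ", "),
                 class = "sclipid_config_error")
  }
  for (p in c("spectra", "targets", "samples")) {
    val <- get(p)
    if (is.character(val) && !file.exists(val) && !dir.exists(val)) {
      stop_sclipid("%s path '%s' does not exist", p, val,
                   class = "sclipid_config_error")
    }
  }
  structure(list(spectra = spectra, targets = targets, samples = samples,
                 out_dir = out_dir, thresholds = thresholds, stages = stages,
                 stratify_lipid = stratify_lipid,
                 spectra_format = match.arg(spectra_format),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the single-cell lipid profiling pipeline
#'
#' Executes the configured stage prefix, writing per-stage CSVs
#' (`matches.csv`, `raw_matrix.csv`, `sample_qc.csv`, `lipid_qc.csv`,
#' `normalized_matrix.csv`, `tiers.csv`, `genotype_tests.csv`,
#' `stratified_tests.csv`, `population_profiles.csv`) and a
#' `manifest.json` recording thresholds, seed, package version and
#' per-stage sample/lipid counts. Any stage error aborts with the stage
#' name attached.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  manifest <- list(
    package = "sclipid",
    version = as.character(utils::packageVersion("sclipid")),
    seed = config$seed,
    stages = config$stages,
    thresholds = unclass(th),
    counts = list()
  )
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop_sclipid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e), class = "sclipid_pipeline_error")
    })
  }

  spectra <- if (is.character(config$spectra)) {
    read_spectra(config$spectra, config$spectra_format)
  } else {
    config$spectra
  }
  targets <- if (is.character(config$targets)) {
    read_targets(config$targets)
  } else {
    .validate_targets(config$targets)
  }
  samples <- if (is.character(config$samples)) {
    read_samples(config$samples)
  } else {
    validate_samples(config$samples)
  }

  run_stage("match", function() {
    m <- match_all(spectra, targets, th)
    utils::write.csv(m$matches, file.path(config$out_dir, "matches.csv"),
                     row.names = FALSE)
    write_matrix(m$raw, file.path(config$out_dir, "raw_matrix.csv"))
    state$matches <- m$matches
    state$raw <- m$raw
    manifest$counts$n_spectra <<- length(spectra)
    manifest$counts$n_lipids_panel <<- nrow(targets)
    blanks <- samples$sample_id[samples$sample_type == "blank"]
    if (length(blanks) > 0L) {
      bl <- blank_assessment(spectra[vapply(spectra, `[[`, "", "sample_id")
                                     %in% blanks],
                             targets[targets$name %in% th$marker_lipids, ,
                                     drop = FALSE],
                             ppm_max = th$ppm_max)
      utils::write.csv(bl, file.path(config$out_dir, "blank_assessment.csv"),
                       row.names = FALSE)
    }
  })

  run_stage("sample_qc", function() {
    qc <- sample_qc(state$matches, state$raw, samples, th)
    utils::write.csv(qc, file.path(config$out_dir, "sample_qc.csv"),
                     row.names = FALSE)
    state$qc <- qc
    state$cells <- passing_cells(qc)
    manifest$counts$n_single_cell <<- nrow(qc)
    manifest$counts$n_failed <<- sum(qc$status == "failed_no_marker")
    manifest$counts$n_doublet <<- sum(qc$status == "excluded_doublet")
    manifest$counts$n_pass <<- length(state$cells)
  })

  run_stage("lipid_qc", function() {
    reports <- lapply(unique(samples$experiment_id), function(e) {
      ids <- samples$sample_id[samples$experiment_id == e]
      apply_filters(state$matches[state$matches$sample_id %in% ids, ,
                                  drop = FALSE],
                    subset_matrix(state$raw,
                                  samples = intersect(ids,
                                                      rownames(state$raw$values))),
                    samples[samples$experiment_id == e, , drop = FALSE],
                    intersect(state$cells, ids), th, experiment_id = e)
    })
    report <- do.call(rbind, reports)
    utils::write.csv(report, file.path(config$out_dir, "lipid_qc.csv"),
                     row.names = FALSE)
    state$lipid_qc <- report
    manifest$counts$n_lipids_passing <<-
      length(unique(report$lipid_name[report$passes]))
  })

  run_stage("normalize", function() {
    keep <- c(state$cells,
              samples$sample_id[samples$sample_type %in%
                                  c("qc_pool", "curve_standard")])
    keep <- intersect(rownames(state$raw$values), keep)
    sub <- subset_matrix(state$raw, samples = keep)
    detected <- rowSums(!is.na(sub$values)) > 0L
    norm <- total_signal_normalize(subset_matrix(sub,
                                                 samples = keep[detected]))
    write_matrix(norm, file.path(config$out_dir, "normalized_matrix.csv"))
    state$norm <- norm
    qc_wells <- samples$sample_id[samples$sample_type == "qc_pool"]
    if (length(unique(samples$plate[samples$sample_id %in% qc_wells])) >= 2L) {
      batch <- plate_batch_check(state$raw, samples)
      utils::write.csv(batch, file.path(config$out_dir, "batch_check.csv"),
                       row.names = FALSE)
    }
    ord <- injection_order_check(norm, samples, seed = config$seed)
    utils::write.csv(ord, file.path(config$out_dir, "injection_order.csv"),
                     row.names = FALSE)
  })

  run_stage("tiers", function() {
    tiers <- assign_tiers(state$lipid_qc)
    utils::write.csv(tiers, file.path(config$out_dir, "tiers.csv"),
                     row.names = FALSE)
    manifest$counts$tier_levels <<- as.list(table(tiers$level))
  })

  run_stage("stats", function() {
    cells_in_norm <- intersect(state$cells, rownames(state$norm$values))
    pop <- population_profiles(state$norm, samples, cells = cells_in_norm)
    write_matrix(pop$profiles,
                 file.path(config$out_dir, "population_profiles.csv"))
    gt <- genotype_tests(state$norm, samples, cells = cells_in_norm,
                         targets = targets)
    utils::write.csv(gt, file.path(config$out_dir, "genotype_tests.csv"),
                     row.names = FALSE)
    cohort <- stratify_by_lipid(state$norm, samples,
                                lipid = config$stratify_lipid,
                                cells = cells_in_norm)
    st <- stratified_tests(state$norm, cohort, targets = targets)
    utils::write.csv(st, file.path(config$out_dir, "stratified_tests.csv"),
                     row.names = FALSE)
  })

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
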