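#' @title Lipid target panels
#' @description A lipid target is a sum-composition annotation (head-group
#'   class plus total acyl carbons and double bonds, e.g. "PC 34:1") together
#'   with the m/z at which its chosen adduct is expected in the spectrum.
#'   Panels are plain data frames with one row per target.
#' @name lipid-targets
NULL

.lipid_classes <- c("PC", "PE", "SM", "Cer", "DG", "PS", "TG")

# Monoisotopic atomic masses (CODATA/IUPAC) and the proton mass used for
# [M+H]+ adduct m/z.
.atomic_mass <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, P = 30.97376163)
.proton_mass <- 1.007276466812

# Molecular formula of a sum-composition lipid as a function of total acyl
# carbons n and double bonds d. Diacyl glycerophospholipids and d-backbone
# sphingolipids are assumed.
.lipid_formula <- function(lipid_class, n, d) {
  switch(lipid_class,
    PC  = c(C = n + 8, H = 2 * n - 2 * d + 16, N = 1, O = 8,  P = 1),
    PE  = c(C = n + 5, H = 2 * n - 2 * d + 10, N = 1, O = 8,  P = 1),
    PS  = c(C = n + 6, H = 2 * n - 2 * d + 10, N = 1, O = 10, P = 1),
    SM  = c(C = n + 5, H = 2 * n - 2 * d + 13, N = 2, O = 6,  P = 1),
    Cer = c(C = n,     H = 2 * n - 2 * d + 1,  N = 1, O = 3,  P = 0),
    DG  = c(C = n + 3, H = 2 * n - 2 * d + 4,  N = 0, O = 5,  P = 0),
    TG  = c(C = n + 3, H = 2 * n - 2 * d + 2,  N = 0, O = 6,  P = 0),
    stop_sclipid("unknown lipid class '%s'", lipid_class)
  )
}

#' Theoretical [M+H]+ m/z of a sum-composition lipid
#'
#' Computes the protonated monoisotopic m/z from the molecular formula
#' implied by the class and the total carbon:double-bond composition.
#' Used to build the illustrative target panel; any measured panel can be
#' supplied instead via [read_targets()].
#'
#' @param lipid_class One of PC, PE, SM, Cer, DG, PS, TG.
#' @param carbons Total acyl carbons (>= 10).
#' @param double_bonds Total double bonds (>= 0).
#' @return m/z in Da.
#' @examples
#' lipid_mz("PC", 34, 1)  # 760.5851
#' @export
lipid_mz <- function(lipid_class, carbons, double_bonds) {
  lipid_class <- match.arg(lipid_class, .lipid_classes)
  f <- .lipid_formula(lipid_class, carbons, double_bonds)
  sum(f * .atomic_mass[names(f)]) + .proton_mass
}

.parse_lipid_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+) ([0-9]+):([0-9]+)$", name))[[1L]]
  if (length(m) != 4L) {
    stop_sclipid("lipid name '%s' does not follow '<CLASS> <carbons>:<double_bonds>'",
                 name, class = "sclipid_parse_error")
  }
  list(lipid_class = m[2L], carbons = as.integer(m[3L]),
       double_bonds = as.integer(m[4L]))
}

.validate_targets <- function(targets, what = "target panel") {
  assert_columns(targets, c("name", "lipid_class", "carbons", "double_bonds",
                            "adduct", "target_mz"), what)
  if (anyDuplicated(targets$name)) {
    dup <- unique(targets$name[duplicated(targets$name)])
    stop_sclipid("%s has duplicated lipid name(s): %s", what,
                 paste(dup, collapse = ", "), class = "sclipid_validation_error")
  }
  bad <- setdiff(unique(targets$lipid_class), .lipid_classes)
  if (length(bad) > 0L) {
    stop_sclipid("%s has unknown lipid class(es): %s (known: %s)", what,
                 paste(bad, collapse = ", "),
                 paste(.lipid_classes, collapse = ", "),
                 class = "sclipid_validation_error")
  }
  if (any(!is.finite(targets$target_mz)) || any(targets$target_mz <= 0)) {
    stop_sclipid("%s has non-positive or missing target_mz", what,
                 class = "sclipid_validation_error")
  }
  if (any(targets$carbons < 10L)) {
    stop_sclipid("%s has carbons < 10", what, class = "sclipid_validation_error")
  }
  if (any(targets$double_bonds < 0L)) {
    stop_sclipid("%s has negative double_bonds", what,
                 class = "sclipid_validation_error")
  }
  targets
}

#' Build a lipid target panel from sum-composition names
#'
#' @param names Character vector of names in the grammar
#'   `"<CLASS> <carbons>:<double_bonds>"`, e.g. `"PC 34:1"`.
#' @param adduct Adduct label recorded for every target (m/z is computed as
#'   the protonated monoisotopic mass).
#' @return A target panel data frame with columns `name`, `lipid_class`,
#'   `carbons`, `double_bonds`, `adduct`, `target_mz`.
#' @examples
#' lipid_panel(c("PC 34:1", "PE 36:2"))
#' @export
lipid_panel <- function(names, adduct = "[M+H]+") {
  parsed <- lapply(names, .parse_lipid_name)
  out <- data.frame(
    name = names,
    lipid_class = vapply(parsed, `[[`, "", "lipid_class"),
    carbons = vapply(parsed, `[[`, 0L, "carbons"),
    double_bonds = vapply(parsed, `[[`, 0L, "double_bonds"),
    adduct = adduct,
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(out$lipid_class), .lipid_classes)
  if (length(bad) > 0L) {
    stop_sclipid("unknown lipid class(es): %s (known: %s)",
                 paste(bad, collapse = ", "),
                 paste(.lipid_classes, collapse = ", "),
                 class = "sclipid_validation_error")
  }
  out$target_mz <- mapply(lipid_mz, out$lipid_class, out$carbons,
                          out$double_bonds)
  .validate_targets(out)
}

#' The default 37-lipid illustrative panel
#'
#' The panel of 25 PC, 9 PE and 3 SM sum compositions measurable from a
#' single dopaminergic neuron, with synthetic [M+H]+ m/z values computed
#' from the sum-composition molecular formulas (a public mass reference,
#' not instrument-calibrated values).
#'
#' @return A target panel data frame (see [lipid_panel()]).
#' @examples
#' head(default_panel())
#' @export
default_panel <- function() {
  path <- system.file("extdata", "lipid_panel_synthetic.csv",
                      package = "sclipid", mustWork = TRUE)
  read_targets(path)
}

#' Read a lipid target panel from CSV
#'
#' The CSV must have a header with columns `name`, `lipid_class`, `carbons`,
#' `double_bonds`, `adduct`, `target_mz`. Names must be unique and classes
#' drawn from the supported enumeration; violations raise a validation error
#' rather than being coerced.
#'
#' @param path CSV file path.
#' @return A validated target panel data frame.
#' @seealso [write_targets()], [lipid_panel()]
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) {
    stop_sclipid("target file '%s' does not exist", path,
                 class = "sclipid_parse_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df <- assert_columns(df, c("name", "lipid_class", "carbons", "double_bonds",
                             "adduct", "target_mz"), sprintf("'%s'", path))
  df$carbons <- as.integer(df$carbons)
  df$double_bonds <- as.integer(df$double_bonds)
  df$target_mz <- as.numeric(df$target_mz)
  .validate_targets(df, what = sprintf("'%s'", path))
}

#' Write a lipid target panel to CSV
#'
#' @param targets A target panel data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  targets <- .validate_targets(targets)
  utils::write.csv(targets, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
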