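# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as plain linear scans / explicit loops,
# sharing no code path with the package internals.

# linear-scan closest peak with the same tie rules (distance, then higher
# intensity, then lower m/z)
brute_closest <- function(spec, target_mz, window_ppm) {
  mz <- spec$peaks$mz
  it <- spec$peaks$intensity
  if (length(mz) == 0L) return(NULL)
  d <- abs(mz - target_mz)
  tol <- if (is.finite(window_ppm)) window_ppm * target_mz / 1e6 else Inf
  inside <- which(d <= tol)
  if (length(inside) == 0L) return(NULL)
  dmin <- min(d[inside])
  best <- inside[d[inside] == dmin]
  if (length(best) > 1L) best <- best[it[best] == max(it[best])]
  if (length(best) > 1L) best <- best[which.min(mz[best])]
  list(mz = mz[best], intensity = it[best],
       deviation_ppm = d[best] / target_mz * 1e6)
}

# random centroid spectrum for property tests
random_spectrum <- function(id, n = 200, lo = 650, hi = 900) {
  spectrum(id, mz = runif(n, lo, hi), intensity = rexp(n, 1 / 50))
}

# explicit-loop recomputation of the iterative per-plate doublet rule
brute_doublets <- function(values, plates, k, frac_min) {
  flagged <- rep(FALSE, nrow(values))
  names(flagged) <- rownames(values)
  for (p in unique(plates)) {
    rows <- which(plates == p)
    if (length(rows) < 3L) next
    fl <- rep(FALSE, length(rows))
    repeat {
      ref <- rows[!fl]
      if (length(ref) < 3L) break
      verdict <- logical(length(rows))
      for (ri in seq_along(rows)) {
        x <- values[rows[ri], ]
        n_hi <- 0L; n_det <- 0L
        for (j in seq_len(ncol(values))) {
          if (is.na(x[j])) next
          n_det <- n_det + 1L
          col <- values[ref, j]
          col <- col[!is.na(col)]
          if (length(col) == 0L) next
          if (x[j] > mean(col) + k * sd(col)) n_hi <- n_hi + 1L
        }
        verdict[ri] <- n_det > 0L && (n_hi / n_det) >= frac_min
      }
      if (identical(verdict, fl)) break
      fl <- verdict
    }
    flagged[rows] <- fl
  }
  flagged
}

# small, fast simulation configuration used across module tests
small_config <- function(seed, ...) {
  simulation_config(n_plates = 2, wells_per_plate = 48, seed = seed, ...)
}

# digitized presence-percentage matrix shipped with the package
presence_matrix <- function() {
  path <- system.file("extdata", "presence_reference.csv", package = "sclipid")
  df <- utils::read.csv(path, comment.char = "#")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$name
  m
}
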