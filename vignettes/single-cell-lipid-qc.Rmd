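---
title: "Single-cell lipid profiling: model, quality control and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell lipid profiling: model, quality control and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclipid)
```

## The measurement problem

Direct-infusion single-cell lipidomics (for example liquid extraction
surface analysis, LESA-MS) dispenses one FACS-sorted cell per well of a
multi-well plate, extracts it, and records a single centroided MS1
spectrum per well. Compared with bulk lipidomics the signals are weak, the
mass accuracy is slightly degraded, many species fall below the lower
limit of detection (LLOD) in a fraction of cells, and two well-level
failure modes appear that bulk assays do not have: the extraction can
*miss* the cell (a failed well that contains only background), and the
sorter can dispense *two* cells into one well (a doublet, which inflates
every lipid signal roughly two-fold). `sclipid` implements the complete
processing chain from per-well peak lists to single-cell heterogeneity
statistics, together with a synthetic generator of the whole study design
so that every stage can be validated against a known truth.

## The data model

A *target* is a sum-composition lipid annotation — head-group class plus
total acyl carbons and double bonds, e.g. `PC 34:1` — with the m/z at
which its adduct is expected. Fragmentation of single-cell signals is not
practical, so annotation never goes deeper than sum composition. The
shipped 37-lipid panel (25 PC, 9 PE, 3 SM) carries *synthetic* `[M+H]+`
m/z values computed from the sum-composition molecular formulas; any
instrument-calibrated panel can be supplied as a CSV instead.

For a single-cell well $i$ and lipid $\ell$ the generator draws the raw
intensity as

$$ I_{i\ell} \;=\; b_\ell \, s_i \, p_{plate(i)} \, g_\ell(geno_i)\,
   e^{\varepsilon_{i\ell}}, \qquad \varepsilon_{i\ell} \sim
   N(0, \sigma_\varepsilon^2), $$

with $b_\ell$ the per-cell base abundance, $s_i$ a lognormal cell-size
factor (mean 1), $p$ a lognormal plate batch factor and $g$ a genotype
effect. Doublets draw $s_i$ from twice the size distribution; failed
wells lack the two marker lipids; blanks contain only background peaks
(Poisson-distributed along m/z with exponential intensities — the
simplest model that exercises closest-peak logic and blank deviation
statistics). Peak positions are the target m/z perturbed by
$N(0, \sigma_{ppm})$ ppm, and peaks below the LLOD are dropped, which is
what produces missing values downstream. Missing is always a distinct
state from zero: a value below the LLOD carries no magnitude.

### Generator defaults and what they emulate

| parameter | default | meaning |
|---|---|---|
| `n_plates` x `wells_per_plate` | 7 x 96 | one experiment of the study design |
| `genotypes`, `n_replicates` | WT/A53T, 4 | two isogenic lines, four biological replicates |
| `qc_per_plate`, `qc_scale` | 6, 10 | pooled QC wells on every plate, ~10 cells of material |
| `blank_fraction` | 0.10 | extraction blanks spread over the plates |
| `failed_fraction`, `doublet_fraction` | 0.05, 0.05 | FACS/extraction error rates |
| `cell_size_cv` | 0.05 | spread of per-cell lipid content after tight FACS gating |
| `lognormal_noise_sd` | 0.05 | multiplicative technical noise (log-SD) |
| `ppm_jitter_sd` | 2 ppm | mass error of true signals |
| `plate_batch_effect_sd` | 0.3 | multiplicative plate batch factor (log-SD) |
| `abundance_distribution_shape` | 2 | decades spanned by the abundance ladder |
| `bimodality_fraction` | 0.6 | mutant cells in the low-PC 36:2 mode |

The abundance ladder is strongly non-linear (geometric over two decades),
with the two marker lipids `PC 34:1` and `PC 36:2` at the top — these are
the most abundant species and the ones whose joint absence defines a
failed well. The mutant genotype carries multiplicative deficits in
PC 36:2 (as a two-component mixture: a `bimodality_fraction` of mutant
cells sit in a low mode at half the wild-type level), PC 36:1, PC 34:2
and PC 32:0.

The dispersion defaults describe the *favourable* regime of abundant,
well-detected lipids in tightly gated cells: a 5% cell-size CV and 5%
technical noise. They were fixed by working the doublet-exclusion rule
forward: a doublet is only recognisable as "all lipids high at once" when
the per-lipid spread among singlets is small compared with the two-fold
size signature, so a generator with much larger dispersion would produce
data in which the published rule cannot work for *any* implementation.
Real single-cell data are noisier than this; passing the recovery tests
therefore shows the pipeline's logic is correct, not that any given
instrument will achieve these error rates. Features of real data the
generator deliberately omits: isotope envelopes, adduct chemistry,
chromatography, correlated (class-wise) biological regulation, and
heavy-tailed background.

## Signal matching

For every (spectrum, target) pair the *closest peak* within a `ppm_max`
window (default 10 ppm) is found by binary bracketing over the sorted
peak list; ties on distance go to the higher-intensity peak, then to the
lower m/z (favouring signal over noise, deterministically). Deviations
are reported unsigned, as $|m/z_{obs} - m/z_{target}|/m/z_{target}
\times 10^6$.

The signal-to-noise ratio of a matched peak is its intensity over the
median intensity of the *other* peaks within ±0.5 Da. The half-width was
chosen as half the nominal mass spacing because in this panel the closest
pair of genuine targets sits 0.95 Da apart: a ±1 Da window would count a
neighbouring lipid's signal as "noise". When the window is empty the
noise falls back to the 5th percentile of all peak intensities in the
spectrum, and to +Inf S/N when even that is zero (a lone peak). A match
is *detected* when deviation <= `ppm_max` **and** S/N > `snr_min`
(default 1.5, strictly greater — a peak at exactly 1.5 fails).

Blank wells are assessed with a *global* closest-peak search (no ppm
window), because the informative quantity there is how far the nearest
background signal sits from the target mass — tens to thousands of ppm —
whereas true cell signals sit within a few ppm.

## Sample-level QC

Exclusion runs in two steps, in this order:

1. **Failed wells.** A single-cell well fails only when *neither* marker
   lipid (`PC 34:1`, `PC 36:2`) is detected; one detected marker
   suffices. Blanks, QCs and curve wells are never classified.
2. **Doublets.** On the *raw* matrix (normalization would erase the
   doubling signature), per lipid a mean and SD are computed over passing
   single-cell wells of the same plate, and a well is excluded when at
   least 80% of *its detected* lipids lie above
   mean + 2.5 SD. The reference is refined iteratively: wells flagged in
   one pass are removed from the reference and the statistics recomputed
   until the flagged set is stable. This masking correction is needed
   because doublets inside the reference inflate the SD enough to hide
   one another — with ~5% doublets the single-pass rule caps out near 80%
   sensitivity no matter how clean the data. The single-pass verdict
   remains available (`detect_doublets(iterate = FALSE)`), and the
   reference can be switched to the whole study
   (`qc_thresholds(doublet_reference = "global")`), though raw
   intensities carry plate batch effects, so per-plate is the default.
   The 80% denominator counts the lipids detected in that well, not the
   whole panel: an undetected lipid cannot testify either way.

Groups with fewer than three evaluable wells return `not_evaluable`,
never a silent pass.

## Lipid-level QC and confidence tiers

Within an experiment a lipid is *successfully measured* when it passes
all four filters: median deviation of detected matches <= 10 ppm; median
S/N > 1.5; Pearson r > 0.5 between intensity and cell number in the
multi-cell "standard" curve wells (not evaluable — and failing — with
fewer than 3 paired points, fewer than 3 distinct count levels, or a
constant vector); and detection in at least 5% of passing single cells.
The 5% is *inclusive*, so a lipid present in exactly 5.0% of cells
passes. (A companion description of the same protocol quotes 10%; 5% is
the default here and the threshold is a parameter.) Per-lipid deviation
and S/N aggregate by median for robustness; the mean is available by
flag.

Across experiments, lipids are graded: level 1 = passed every
experiment, level 3 = passed exactly one, level 2 = anything in between
(with three experiments: two of three). Lipids passing none are dropped
with a count. On the shipped three-experiment presence table the >= 5%
rule yields exactly 37 level-1 species: 25 PC, 9 PE and 3 SM.

## Normalization and batch checks

Cell size is the dominant driver of measured abundance, and internal
standards cannot correct single-cell data (the amount of lipid per well
is itself the biological signal, so lipid and standard intensities
decorrelate). Instead each sample is divided by its total detected
signal, giving unit-sum composition profiles. The denominator is the sum
over detected *panel* lipids, not total ion current: the background is
not biological material. The operation is idempotent, invariant to any
per-sample rescaling, and by construction removes every per-sample
multiplicative factor — cell size and plate batch effects alike.

Two checks verify this on the pooled QC wells: a one-way between-plate
ANOVA per lipid (Kruskal–Wallis by flag; the parametric default matches
the roughly lognormal QC setting), run on raw and on normalized values —
a batch effect is "removed" when raw p < 0.05 and normalized p >= 0.05 —
and a Spearman correlation of the first two principal-component scores of
the normalized profiles against injection order, with permutation
p-values. For the ordination, missing values are imputed at half the
per-lipid minimum (configurable); zero-variance score vectors return an
association of 0 by convention. Lipids with no variance across QCs give
p = 1 rather than a numerical failure.

## Heterogeneity statistics

*Population profiles* are per-(genotype, replicate) means over detected
values — the quantity a bulk assay would report. Group contrasts use a
Gaussian linear model on log-transformed unit-sum abundances (a
two-sided Wald test; with one binary covariate this equals the
equal-variance t test, which the suite exploits as a closed-form
oracle). Log-Gaussian was chosen because the noise model is
multiplicative; the raw-scale identity-link fit is available by flag.
Fold changes are always ratios of group means on the natural scale, and
degenerate inputs (fewer than 3 values per group, or zero variance)
return `not_evaluable` rather than NaN.

Stratification by a reference lipid (default `PC 36:2`) uses a median
split within genotype — balanced strata with no free parameter; ties at
the median go to the low stratum and an all-tied group is flagged
degenerate. Cells missing the lipid are unassigned and excluded; fewer
than 4 assignable cells per genotype is an error. High-vs-low contrasts
within each genotype then reuse the group-test machinery with fold
changes relative to the *low* stratum, including the derived `PC/PE`
variable (sum of detected PC over sum of detected PE; undefined when no
PE is detected). Because numerator and denominator share the sample's
normalization divisor, `PC/PE` is invariant to total-signal
normalization. Raw p-values are reported with Benjamini–Hochberg
q-values alongside; the raw p < 0.05 rule is the default decision
threshold. Missing values are handled by pairwise deletion — below-LLOD
observations are informative but carry no magnitude, which is a
documented limitation. Replicate is not included as a covariate by
default.

## Reproducibility and numerical choices

Every stochastic component flows from a single integer seed:
`simulate_experiment()` consumes `seed` directly, the standard curve of
experiment *e* uses `seed + e`, and the permutation tests take an
explicit seed from the pipeline configuration. Two runs with the same
configuration are byte-identical, and the RNG state of the calling
session is restored afterwards. Tie-breaks (closest-peak, median split)
are exact and deterministic. Unit-sum validation uses a 1e-9 absolute
tolerance; idempotence and scale-invariance hold to 1e-12.

Problem sizes in the shipped tests and acceptance script were chosen to
exercise the study design at full scale exactly once (one 7 x 96
experiment, ~560 cells) and smaller 1–2-plate configurations elsewhere;
oracle-equivalence properties run on >= 1,000 randomized instances; the
null calibration of the group test uses 1,000 replicates at n = 40 + 40.

## Known limitations

* Detection in the generator is a sharp LLOD threshold, so simulated
  presence fractions transition more steeply across the abundance ladder
  than the gradual percentages seen in real panels.
* The doublet rule's performance degrades quickly as cell-size CV grows;
  on real data with > 15% size spread the published thresholds would need
  re-examination.
* PLS-DA modelling and fragmentation-based identification are out of
  scope; `injection_order_check()` provides the ordination hook used for
  run-order QC.
* The S/N estimate is implementation-defined (the source protocol leaves
  it unstated); the local-median definition here is robust and
  deterministic but not comparable across instruments.
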