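---
title: "Methods: dual-channel co-aggregate detection and counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel co-aggregate detection and counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualspot)
```

# Overview

`dualspot` implements object-based co-localization analysis for surface
immunoassays that report protein co-aggregates as coincident fluorescent
particles in paired images: a red channel targeting α-synuclein and a
far-red ("blue") channel targeting amylin. A sample's readout is the number
of red/blue particle pairs closer than a matching radius, corrected for the
number of pairs expected by chance.

The package covers the full path from raw images to cohort statistics:

1. **Synthetic data** with exact ground truth (`generate_field()`,
   `generate_dilution_series()`, `generate_cohort()`,
   `simulate_sensorgram()`), so every downstream stage is testable offline.
2. **Detection** per channel (`detect_spots()`).
3. **Co-localization** by one-to-one matching with a chance-overlap
   correction (`match_spots()`, `coloc_summary()`).
4. **Assay QC**: well aggregation, dilution linearity, batch-failure rules
   (`summarize_well()`, `dilution_linearity()`, `qc_batch()`).
5. **Cohort statistics**: t-test, one-way ANOVA with Tukey HSD, bootstrap
   ROC/AUC, Spearman correlation (`compare_two_groups()`, `compare_multi()`,
   `roc()`, `spearman_corr()`).
6. **Binding kinetics**: the 1:1 Langmuir model for SPR sensorgrams
   (`kd_from_rates()`, `fit_1to1()`).

# Synthetic field model

A field is a pair of 16-bit images of the same surface region. True
co-aggregates appear in both channels; singletons appear in one. The
generator draws Poisson numbers of co-localized pairs and per-channel
singletons, places them uniformly (keeping a 3-sigma margin from the
border so no truncated spot biases detector evaluation), and renders each
particle as an isotropic 2-D Gaussian (the diffraction-limited point-spread
function) with log-normal peak amplitude. The blue partner of a pair is
displaced by isotropic Gaussian jitter (default sd 1 px), modeling residual
chromatic/stage registration error. Noise follows the CCD model: Poisson
shot noise on signal plus background, additive Gaussian read noise,
rounding and clipping to the 16-bit range.

Peak signal-to-noise ratio is defined as the median peak amplitude divided
by the background noise sd, `sqrt(background + read_noise_sd^2)`. Defaults
put the field at peak SNR 10 with 30 pairs and 20 singletons per channel on
a 512×512 px field at 0.325 µm/px — a moderately loaded, resolvable
density; at 256² the same load already merges enough neighboring spots to
cost several percent recall, which is a property of the optics being
emulated, not of the detector.

```{r field}
fg <- generate_field(field_params(seed = 42))
fg$field
fg$truth$coloc_fraction
```

# Detection

Each channel is processed independently (exposures differ between channels,
so intensities are never compared across them). `detect_spots()` combines
two operators:

* **Contour detection**: threshold, label connected components
  (`EBImage::bwlabel`), filter by area and circularity `4πA/P²`, report
  intensity-weighted sub-pixel centroids and equivalent-disc radii.
* **Hough circle detection**: on the histogram-equalized image, gradient
  edge pixels vote along their gradient direction at each candidate radius;
  accumulator peaks above a fraction of the full circumference become
  circles, deduplicated by non-maximum suppression.

Detections from the two operators within `merge_dist_px` collapse to one
spot (contour geometry wins; the spot is labeled `"merged"`).

Three numerical choices deserve justification:

* **Thresholding on the raw histogram.** Global histogram equalization of a
  background-dominated image spreads the background over the full 8-bit
  range, making its histogram nearly uniform; Otsu's criterion then selects
  a mid-range threshold that admits about half the background. Because
  equalization is monotone, thresholding the raw image selects the same
  family of pixel sets, so the contour threshold is computed on the raw
  histogram and floored at `median + k·MAD` — on a near-blank field Otsu
  alone must split a pure-noise histogram, and the robust floor is what
  keeps such fields empty.
* **Hough interior-intensity and contrast gates.** On blank fields the
  equalized image is pure noise stretched over 0–255 and gradient voting
  produces spurious circles (~0.7/field without the gate). A true particle's
  interior sits at the top of the equalized range, so candidates below
  `hough_min_intensity` are rejected. Additionally, a candidate must
  outshine its surrounding annulus (radius r..2r) on the raw scale:
  very bright particles otherwise produce displaced "ghost" rings whose
  annulus contains the particle core.
* **Circularity bound 0.3.** Two particles closer than about 2 PSF widths
  merge into one dumbbell-shaped component whose circularity drops well
  below the textbook 0.5; a 0.3 bound retains those while still rejecting
  filamentous debris.

All detector parameters are explicit, documented defaults in
`detect_config()`; they were calibrated on synthetic fields with seeds
disjoint from the test-suite seeds and then frozen.

```{r detect}
spots <- detect_spots(fg$field$red_image, detect_config(), channel = "red")
head(spots, 3)
```

# Co-localization

`match_spots()` builds the bipartite graph of red/blue detections with an
edge whenever the center distance is at most `d_max_px` (default 3 px) and
computes a maximum-cardinality one-to-one matching; among maximum
matchings, total distance is minimized (weights `C − d` with `C` large
enough that cardinality always dominates, solved by
`igraph::max_bipartite_match`). Greedy nearest-neighbor pairing is *not*
equivalent and undercounts in crowded fields.

Under complete spatial randomness, two independent point sets of sizes
`n_red` and `n_blue` on area `A` produce
`n_red · n_blue · π · d_max² / A` coincidental pairs in expectation (dilute
regime). `coloc_summary()` reports the raw matched count, this expectation,
the chance-corrected count `max(0, n_coloc − expected)`, and the
co-localization rate `n_coloc / n_red`.

```{r coloc}
res <- coloc_field(fg$field, detect_config(), d_max_px = 3)
res$summary
```

# Assay QC

`summarize_well()` sums counts and imaged areas over a well's fields and
reports densities per mm², making acquisitions from different platforms
comparable. `dilution_linearity()` fits the log–log slope of count against
relative concentration for a serial dilution of the aggregate standard
(ideal slope 1 in the dilute regime). Steps below the `min_count`
quantitation limit can be excluded: far down a 5-fold/7-step series the
true signal falls beneath the detector's residual false-count floor, and
sub-quantitation steps measure that floor rather than the analyte.

`qc_batch()` applies the batch-failure rules: `poor_standard_curve` when
the standard counts are not monotone over the informative steps (those
above the blank floor — Poisson-level inversions among sub-blank tail
steps carry no curve information), when the concentration/count Spearman
correlation falls below 0.9, or when the top standard does not exceed the
blank; `amylin_bleedthrough` when an α-synuclein-only standard shows total
blue counts above 10% of total red counts. The reference protocol states
these failure modes qualitatively; the numeric thresholds are this
package's explicit, overridable defaults (`qc_thresholds()`).

# Cohort statistics

The statistics mirror standard biomarker practice: Student's t-test
(pooled by default, Welch optional), one-way ANOVA with Tukey HSD for three
or more groups, Spearman rank correlation, and ROC/AUC. The AUC is computed
by the mid-rank Mann–Whitney formula (ties get half credit) with a
stratified percentile bootstrap CI, deterministic given its seed. The
synthetic cohort generator produces negative-binomial per-sample counts
(Gamma-mixed Poisson readouts, 2 replicates × 6 fields) and a covariate
rank-coupled to the co-aggregate count through a Gaussian copula, using the
exact relation `ρ_pearson = 2 sin(π ρ_spearman / 6)` for the latent
correlation.

```{r stats}
tab <- generate_cohort(cohort_params(seed = 7))
roc(tab$coagg_count, tab$group == "PD", n_boot = 500, seed = 1)
```

# Kinetics

Antibody/antigen binding follows the 1:1 Langmuir model:
`R(t) = Req (1 − e^{−(ka·C + kd) t})` during association with plateau
`Req = Rmax·C/(C + KD)`, exponential decay at rate `kd` during
dissociation, and `KD = kd/ka`. `fit_1to1()` fits `(ka, kd, Rmax)` jointly
to any number of sensorgrams by Levenberg–Marquardt least squares
(`minpack.lm`) on the log scale (enforcing positivity), with starting
values from a linearized plateau analysis (`1/Req` vs `1/C`) and the
dissociation log-slope. Designs that do not identify the parameters — for
example a single concentration far below KD, where only the product
`ka·Rmax` enters — are flagged via the condition number of the Jacobian at
the solution.

```{r kinetics}
kp <- kinetic_params(ka = 5809, kd = 2.136e-3, Rmax = 100)
kd_from_rates(5809, 2.136e-3)
sgs <- lapply(kp$KD * c(0.5, 1, 2), function(C)
  simulate_sensorgram(kp, C, t_assoc = 300, t_dissoc = 300,
                      noise_sd = 1, seed = round(C * 1e9)))
fit_1to1(sgs)
```

# Reproducibility and problem sizes

Every stochastic function takes an explicit seed and leaves the caller's
RNG stream untouched; `derive_seed()` produces independent child streams
from one base seed. The validation suite exercises the package at fixed
design sizes chosen to balance statistical resolution against desk-scale
runtime: 500 exhaustive matching instances (≤8 spots/channel), 200
brute-force AUC instances (n ≤ 30), 10⁴ CSR fields for the chance-overlap
null, 50 fields per co-localization-fraction level, 100 replicate dilution
series, 50 detection benchmark fields, 20 kinetics round-trip seeds, and
2000 null cohorts for type-I-error calibration. The same quantities can be
recomputed from an installed copy with `scripts/acceptance.R`.
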