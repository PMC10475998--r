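---
title: "Quantifying nanoscale pTDP-43 clusters at excitatory synapses: models and methods"
author: "synclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoscale pTDP-43 clusters at excitatory synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synclust)
```

## Scope and scientific problem

`synclust` quantifies phosphorylated TDP-43 (pTDP-43) clusters at the two
major excitatory synapse populations of spinal-cord neuropil — large,
sparse VGLUT1-type presynaptic terminals and small, abundant VGLUT2-type
terminals, each apposed to a PSD95-positive postsynaptic density (PSD).
The package implements four analysis layers:

1. **Spot sizing** — the four-line-profile Gaussian FWHM diameter
   estimator for diffraction-limited puncta, with fit-quality exclusion
   rules;
2. **Segmentation and object colocalization** — macro-style processing
   (rolling-ball background subtraction, Gaussian blur, thresholding,
   particle analysis), binarized-overlap colocalization, synapse subtype
   classification, and per-compartment cluster counting;
3. **Single-molecule localization (SMLM)** — peak fitting, quality
   filtering, DBSCAN clustering, synapse association and Fourier ring
   correlation (FRC) resolution for DNA-PAINT-style data;
4. **Statistics** — the comparison battery applied to those outputs
   (pooled t, Mann–Whitney U, one-/two-way ANOVA, chi-squared
   association, Shapiro–Wilk routing, control normalization).

Because no public microscopy dataset accompanies this analysis setting,
a first-class **synthetic-scene generator** produces ground-truth fields
(synapse geometry, cluster positions and sizes in physical nanometres),
renders them as confocal / Airyscan / g-STED / TIRF images, and simulates
DNA-PAINT-style localization streams. Every stage of the pipeline is
validated against this known truth.

## The synthetic scene model

`scene_params()` fixes the generative conditions:

* Synapse counts are Poisson at the configured densities. The literature
  for this tissue reports no absolute densities or terminal areas, only
  that VGLUT2 terminals are smaller and more abundant; the defaults
  (VGLUT1: 2 per 100 µm², 0.60 µm² mean area; VGLUT2: 8 per 100 µm²,
  0.15 µm², i.e. 4× denser and 4× smaller) encode that ordering and are
  fully configurable.
* Terminals are ellipses with aspect ratio 1.2–2, placed with a hard-core
  constraint (centers farther apart than the sum of long semi-axes) and
  an inset border margin, so structures neither overlap nor clip the
  field edge. Real neuropil is denser and more irregular; the hard-core
  rule is a deliberate simplification that keeps object identity
  unambiguous in the ground truth.
* One PSD is apposed to each terminal edge along a random direction, its
  long axis tangential, penetrating the terminal boundary by 25–50% of
  its short semi-axis. This guarantees the partial overlap that defines a
  synapse downstream while keeping the shared area small.
* Compartment occupancy (probability that a compartment holds ≥ 1
  cluster) defaults to the empirical values 87.6% (VGLUT1 terminals),
  59.6% (VGLUT2 terminals), 46.2% / 45.7% (PSDs of VGLUT1 / VGLUT2
  synapses). Occupied compartments receive `1 + Poisson(0.8)` clusters,
  placed uniformly inside the compartment ellipse (inset 10% so centers
  cannot sit on the boundary).
* True cluster diameters are Normal(120, 25) nm (diameter = FWHM of the
  cluster's Gaussian intensity profile), truncated at 20 nm.
* A `genotype_effect` < 1 shrinks VGLUT1 terminal and VGLUT1-associated
  PSD areas multiplicatively — the disease-arm phenotype.
* 10% of VGLUT1 terminals carry a weak (30% amplitude) VGLUT2 signal,
  exercising the classification rule that VGLUT2 expression never
  disqualifies a VGLUT1 synapse.

Rendering rasterizes structures at pixel centers (nm → pixel by floor
division, pixel `i` centered at `(i − 0.5)·pixel_size`), convolves with a
Gaussian PSF, adds a constant background, and applies Poisson shot noise
on signal + background (no read-noise term — EMCCD/GaAsP shot noise
dominates at these intensities). Modality presets: pixel sizes 85 nm
(confocal), 35 nm (Airyscan), 20 nm (g-STED), 107 nm (SMLM camera, i.e. a
16 µm EMCCD pixel behind a 60× objective and 2.5× expander). PSF FWHM
defaults — confocal 300 nm, Airyscan 180 nm, g-STED 90 nm — are not
published values but were chosen (once, a priori) so that identical
~120 nm ground truth reproduces the empirically observed ordering of
measured diameters (≈ 315 > 221 > 143 nm) through the convolution law
`FWHM_obs² = FWHM_true² + FWHM_psf²`. All are configurable.

The localization simulator emits, per frame and per cluster, a Poisson
number of binding events uniform in the cluster disc, detected with
isotropic Gaussian error of scale `precision_nm` (default 20 nm, the
reported accuracy of the aptamer-based labelling) and log-normal photon
counts (meanlog log 500, sdlog 0.35 — typical DNA-PAINT event
brightness). What the generator does **not** emulate: aptamer binding
kinetics and dark times, emitter blinking correlations, sample drift,
optical aberrations, read noise, and the unbounded structural diversity
of real neuropil. Passing recovery tests therefore demonstrates that the
algorithms are correct and unbiased under the stated model, not that any
specific biological estimate is accurate for real tissue.

## Spot sizing

`measure_spot_fwhm()` reproduces the plugin-style estimator: four line
profiles (horizontal, vertical, both diagonals; diagonal sample spacing
√2 × pixel) through the integer intensity maximum, each fitted with a
4-parameter Gaussian by Levenberg–Marquardt; the spot diameter is the
mean of the four FWHM values (`FWHM = 2√(2 ln 2)·σ`). Acceptance requires
all four R² ≥ `r2_min` (default 0.8) and the mean FWHM inside
`fwhm_range_nm` (default 40–800 nm); the source procedure states only
"too low" and "out-with the expected ranges", so both cutoffs are
explicit, logged defaults rather than inferred values. Profiles are
centered on the integer maximum without sub-pixel re-centering, matching
the plugin behaviour; overlapping spots are not deblended — maxima closer
than `min_separation` merge to the brighter one, ties to the lower (row,
col) position.

## Segmentation, colocalization, classification

The interactive manual threshold of the original workflow is replaced by
a deterministic rule — Otsu per channel by default, a fixed value by
configuration — trading the blinded human step for reproducibility.
Background subtraction is a true rolling ball (grayscale opening with a
non-flat spherical element); radii above 16 px use the standard
shrink/roll/bilinear-enlarge scheme. Connected components are 4-connected
(2D) / 6-connected (3D), the default particle-analysis convention, and
particles outside `[min_area_px, max_area_px]` (default ≥ 4 px, no upper
bound — the source macros do not state their window) are discarded.

Colocalization is object-based intensity redirection: an object is
colocalized when ≥ 1 of its pixels lies on the other marker's foreground
("any intensity above zero"). Classification follows the published
definitions exactly: a VGLUT1 synapse is a VGLUT1 particle overlapping
PSD95 regardless of VGLUT2; a VGLUT2 synapse is a VGLUT2 particle
overlapping PSD95 with zero VGLUT1 overlap. Each synapse pairs with the
PSD of largest overlap (ties to the lowest label).

Cluster-in-structure counting uses the cluster **centroid** (a cluster
belongs to the structure whose foreground contains its centroid), chosen
as the single rule consistent across the 2D overlap-redirection macro and
the 3D inclusion analysis; an overlap-based alternative is available via
`rule = "overlap"`. Known limitation: when a presynaptic and a
postsynaptic cluster of the same synapse fall within about one PSF width,
their thresholded spots merge and the joint centroid usually stays inside
the (larger) terminal but leaves the (smaller) PSD — measured PSD
occupancy therefore runs a few percentage points below the configured
truth at Airyscan resolution. This is a property of the pixel-based
method itself, and the parameter-recovery tests bound it at under five
percentage points under the default conditions.

## SMLM chain

Frames get a 12 px rolling-ball background subtraction; candidate maxima
are fitted with a 2D Gaussian; photons are the integrated fitted
intensity `2πAσ²`; precision follows the Thompson-style closed form
`√((σ_nm² + a²/12)/N)` (the original plugin's exact estimator is not
stated); signal strength is fitted amplitude over residual noise SD — a
declared definition, not one recovered from the source. Quality filters
(signal ≥ 20, photons ≥ 50, precision ≤ 40 nm) are all inclusive; the
source does not specify inclusivity, and the boundary convention is
frozen in tests. DBSCAN runs with eps 40 nm and minPts 5; border points
join the first-discovered core cluster under deterministic row-order
traversal, and the implementation is tested for exact agreement with a
brute-force reference. Cluster diameter is defined as the **maximum
pairwise member distance** (the source never defines its diameter; a
2·RMS-radius alternative would read roughly 40% smaller on these data).
With 20 nm localization error this maximum-spread statistic reads well
above the true disc diameter — simulated 55 nm clusters measure a median
near 110–130 nm — so diameter medians from this package are comparable
with each other but not directly with figures computed under an unknown
diameter definition.

FRC splits localizations by odd/even frame, renders 10 nm-pixel
histograms (power-of-two grid, ≥ 64), correlates per integer frequency
ring, smooths with a 7-ring running mean, and reports the inverse
frequency at the first crossing of the fixed 1/7 threshold, with an
explicit "unresolved" sentinel when the curve never crosses. At 20 nm
Gaussian error on dense fields the estimate is ≈ 60 nm (about 3× the
error SD); resolutions near 37 nm arise when the effective per-event
error is ≈ 12–15 nm, as is typical after precision filtering.

## Statistics

All tests delegate to standard routines behind a thin, unit-aware
surface (`group_sample` records whether values are animal-level means or
pooled objects): pooled-variance two-sample t (the reported degrees of
freedom in the motivating analyses, e.g. T(8) for 5+5 animals, imply the
pooled form); Mann–Whitney U with midranks, exact p (via the exact U
distribution) for tie-free samples with `n_a·n_b ≤ 400`, otherwise a
tie-corrected normal approximation; one-way ANOVA with Tukey HSD;
two-way ANOVA with Type II sums of squares (appropriate for the
main-effects question on the unbalanced 5-vs-6-animal design);
Pearson chi-squared **without** continuity correction — the reconstructed
worked example (30 and 145 synapses at 80% and 51% containment) gives
χ²(1) = 8.46, which matches the printed 8.5 only without Yates
correction; and a Shapiro–Wilk gate that routes to the parametric branch
at p ≥ 0.05. Group comparisons run on raw values and are normalized to
the control mean (control ↦ 100%) for display only — the genotype F is
scale-invariant, so this choice does not affect inference.

## Pipeline orchestration and problem sizes

`run_airyscan_analysis()` chains render → segment → classify → count →
per-animal aggregation (images are averaged within animal; the animal is
the statistical unit). The parameter-recovery configuration uses 5
animals × 8 images of a 25 µm field (≈ 500 VGLUT1 and ≈ 2000 VGLUT2
synapses), which recovers all four configured occupancies within ±5
percentage points. `run_smlm_analysis()` chains simulate → filter →
DBSCAN → TIRF-mask association → chi-squared, with FRC on a central
12.8 µm crop so the FFT grid stays bounded. `run_group_comparison()`
simulates both arms at the ground-truth level (per-animal log-normal area
scale, CV 5%; logit-normal occupancy jitter, SD 0.15 — chosen to mimic
the between-animal spread visible in published group data) and runs the
full battery; 200 seeded replicates detect the 0.7× VGLUT1 size effect
and keep the null pTDP-43 effects null (each at ≥ 90% of runs). These
problem sizes are the package's validation defaults; all scale through
their configs.

## Numerical choices and degenerate inputs

* Gaussian fits use `minpack.lm`'s Levenberg–Marquardt core directly, so
  zero-residual (noiseless) data converge cleanly; non-convergence or
  σ ≤ 0 yields a `fit_failure` flag, never an exception.
* Flat images give zero maxima at any positive prominence; thresholds
  above the intensity maximum give a valid empty mask; zero marker area
  gives an `NA` density sentinel with a warning; zero accepted spots give
  an explicit empty summary.
* Both-groups-constant t comparisons return p = 1 (equal means) by
  convention; all-identical ANOVA groups return F = 0.
* Determinism: every pipeline derives per-stage 31-bit seeds from the
  master seed; identical configurations reproduce identical outputs
  bit-for-bit.
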