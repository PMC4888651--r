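---
title: "Label-free viability metrics for 3D tumor spheroids from OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free viability metrics for 3D tumor spheroids from OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octspheroid)
```

## Why image-based viability metrics

Three-dimensional tumor spheroid cultures — such as OVCAR5 ovarian cancer
nodules grown on basement-membrane matrix, which self-assemble into
400–700 µm aggregates — are a standard model for avascular metastatic
lesions. The workhorse readout for treatment response in such cultures, the
two-fluorophore Live/Dead assay (calcein AM for live cells, ethidium
homodimer for dead), is terminal, depth-limited, and can misreport killing
outright when therapy perturbs the esterase chemistry the live stain relies
on. Optical coherence tomography images the same cultures label-free to
millimeter depths at micrometer resolution, repeatedly, without touching the
sample.

`octspheroid` implements two treatment-response indices computed purely from
OCT intensity volumes, plus everything needed to validate them without an
instrument: a spectral-domain reconstruction step, per-slice segmentation, a
synthetic phantom generator with exact ground truth, a Live/Dead benchmark,
and longitudinal group statistics.

## The two indices

**Disruption index.** Cell death — apoptotic or necrotic — dissolves
cell–cell adhesion, so treated nodules fragment. Fragmentation raises
surface area faster than it lowers volume. Working per xz cross-sectional
slice (indexed by the slow scan axis $y$), each segmented 2D object
contributes its boundary perimeter $P_i$ and enclosed area $A_i$; with slice
thickness $\Delta y$,

$$\left(\frac{S}{V}\right)_{\text{global}}
  = \frac{\sum_i P_i\,\Delta y}{\sum_i A_i\,\Delta y},$$

a single pooled ratio per well (not a mean of per-object ratios, so
fragmented material carries its own weight). The disruption index is this
ratio normalized to the no-treatment (NT) control and shifted so intact
cultures score zero:

$$\mathrm{DI} = \frac{(S/V)}{(S/V)_{\mathrm{NT}}} - 1.$$

The unshifted ratio (control = 1) is also reported via
`normalize_to_control()`.

**Apoptotic density.** Apoptosis packages cell contents into dense,
refractile vesicles that scatter strongly, appearing as bright bodies inside
nodules. Per nodule, voxels brighter than $1.7\times$ the nodule's mean
intensity (the "70 % above average" rule) form candidates; a size filter
(defaults: 4 µm and 40 µm equivalent-sphere radii) and a distance-transform
watershed yield individual bodies. Then

$$\mathrm{AD} = \frac{\sum_j V_j^{\text{apoptotic}}}{V_{\text{spheroid}}},$$

a dimensionless volume fraction, again reported control-normalized. Because
the threshold is *relative*, the feature mask is invariant under global
intensity rescaling — the suite verifies this exactly.

## Reconstruction

Raw spectral-domain interferograms (one spectrum per A-scan, linear in
wavenumber) are reconstructed A-scan-wise: DC removal, apodization, FFT,
magnitude of the positive-frequency half. With $M$ spectral samples the
image has $M/2$ depth bins; a reflector encoded at depth bin $k$ lands at
output row $k$.

Two deliberate choices:

* **No k-resampling.** The synthetic path controls its own sampling, and
  re-gridding measured spectrometer data is instrument-specific; a
  resampling callable can be applied to the spectra before `raw_bscan()` if
  needed.
* **Window pairing.** `reconstruct_bscan()` defaults to a Hann window, the
  ordinary choice for measured spectra. `simulate_raw_spectra()`, however,
  emits zero-phase cosine combs at exact integer bins, for which the
  rectangular window is *exact* by DFT orthogonality — while Hann's
  transform, $0.5\delta_k - 0.25\delta_{k\pm1}$, sums to zero across the
  flat interior of a constant-reflectivity nodule and hollows it out. All
  phantom round-trips therefore use `window = "none"`; this pairing, not a
  free parameter, is what the round-trip tests exercise.

## Segmentation choices

* **Foreground threshold**: global Otsu over nonzero voxels (the source
  analysis does not state its foreground rule), overridable with a fixed
  threshold; every threshold used is recorded in the outputs.
* **Despeckle**: a 3×3×3 boxcar before thresholding plus a per-slice
  3×3 opening. For *nodule* segmentation this is on by default — the bias is
  a one-voxel surface layer on objects tens of voxels across.
* **Perimeter estimator**: the default is the two-direction Cauchy–Crofton
  estimate, $\frac{\pi}{4}\,(\text{exposed-edge length})$, which is accurate
  to ~1 % on digital disks of radius ≥ 10 px; the raw exposed-pixel-edge
  ("Manhattan") length overestimates smooth outlines by $4/\pi$ (≈ 27 %) and
  is available as `estimator = "edge"` for exact checkability (a 10×10
  square then reports perimeter 40 µm). The stacked-circle convention on a
  digital ball of radius $r$ gives $S/V \to 3\pi/4r$, which the Crofton
  default reproduces within a fraction of a percent.
* **Connectivity**: 3D objects are 6-connected components computed on the
  voxel adjacency graph; per-slice ledgers use 2D labelling per xz frame.
* **Apoptotic thresholding is unsmoothed by default.** On noise-free data a
  sharp per-voxel threshold recovers body volumes essentially exactly,
  whereas pre-blurring biases the volume of 5–15 µm bodies (partial-volume
  shells) and inflates the nodule mean. With speckle, per-voxel
  thresholding of exponentially distributed intensities is meaningless, so
  `smooth = TRUE` turns the boxcar on for detection; the residual bias this
  trades in is the cost of noise suppression.
* **Watershed**: the distance map is an iterative-erosion (city-block)
  transform; seeds are its regional maxima (plateaus merged, dominated
  ridges excluded), thinned so no seed lies within the combined radii of a
  stronger seed — two genuinely distinct touching bodies keep both seeds
  because their centres are at least $r_1 + r_2$ apart. Voxels then join the
  nearest seed of their component; for quasi-spherical bodies that boundary
  is the watershed neck. Ties break in raster order, so the split is
  deterministic.
* **Mean scope**: the 1.7× reference mean is per-nodule by default
  (`mean_scope = "global"` pools all nodule voxels), since the source
  describes "the average intensity of the 3D nodule".

## The phantom generator

`generate_phantom()` renders what the analysis assumes about real cultures:

* quasi-spherical nodules, 400–700 µm diameter by default, at
  non-overlapping random positions;
* intensity = reflectivity × $e^{-2\mu z}$ depth attenuation
  (default $\mu = 5\times10^{-4}\,\mu m^{-1}$, a mild soft-tissue-like
  decay), optionally × unit-mean gamma speckle (shape 1 = fully developed
  exponential speckle);
* apoptosis as bright spheres (default 5–15 µm radius, intensity gain 3)
  placed preferentially in the peripheral shell of the nodule, as seen
  after chemotherapy alone;
* disruption via `apply_fragmentation()`: the requested voxel fraction is
  peeled from each nodule's outside and re-deposited as small detached
  spheres in a surrounding shell, conserving foreground voxel count within
  1 % (losses are logged in the truth object).

Ground truth is exact: the apoptotic fraction is a voxel-count ratio, and
the true surface-to-volume ratio uses the same slice convention as the
metric, so parameter-recovery tests close the loop without circularity in
the *intensity* path.

What the phantom does **not** emulate: real speckle correlation lengths
(noise is i.i.d. per voxel), refraction and shadowing under objects,
sensitivity roll-off, bulk motion, sub-resolution texture from organelles,
or nodules touching the dish or each other. Passing recovery tests
therefore demonstrates the correctness and calibration of the *analysis
chain*, not robustness to every physical artifact of a real instrument.

## Statistics

Group comparisons use the two-tailed, unpaired, pooled-variance Student's
t-test with $df = n_a + n_b - 2$ (`ttest_two_sample()`, a thin wrapper over
`stats::t.test(var.equal = TRUE)` adding the degenerate convention: zero
pooled variance with equal means gives $t = 0, p = 1$; with unequal means it
is an error rather than a fake infinity). Box summaries report type-7
(linear-interpolation) quartiles by default — the convention is recorded in
every output row, and the classical halves rule is available as
`quantile_type = 2` — with whiskers at $Q_3 + 1.5\,\mathrm{IQR}$ /
$Q_1 - 1.5\,\mathrm{IQR}$, clamped to the most extreme non-outlier points.

"Synergy" in `synergy_table()` is operationalized per day and metric as the
combination arm exceeding **both** monotherapies with $p < 0.05$ against the
better one. No multiple-testing correction is applied by default, matching
pairwise reporting practice; Bonferroni is available. No Bliss or Loewe
model is implied.

Degenerate wells (no detected foreground) carry `NA` metrics and are
excluded from group statistics, never imputed.

## Problem sizes used by the tests

The instrument-scale default geometry (1024 × 2048 × 250 voxels at
~1 µm pitch) is impractical for a test suite, so the package's own tests and
the acceptance script run scaled-down conditions, chosen once:

* structural/fragmentation experiments: 64×96×96 voxels at 8 µm pitch,
  two nodules of 220–300 µm diameter;
* apoptotic-body recovery: 140×150×150 voxels at 2.5 µm pitch, one
  300–330 µm nodule, so 5–15 µm bodies span several voxels;
* the longitudinal course: 88×96×96 voxels at 4 µm pitch, one ~300 µm
  nodule per well, bodies 8–15 µm; 4 arms × 5 days × 3 wells;
* watershed fixtures: 16 µm bodies at 2 µm pitch.

The size ordering voxel ≪ body ≪ nodule ≪ volume is preserved throughout,
which is what the analysis actually relies on.

## A short worked example

```{r example, eval = FALSE}
spec <- phantom_spec(grid_shape = c(64, 96, 96), voxel_pitch = c(8, 8, 8),
                     n_spheroids = 2, radius_range = c(110, 150),
                     fragmentation = 0.3, seed = 1)
ph <- generate_phantom(spec)
seg <- segment_nodules(ph$volume)
global_sa_to_v(seg)           # pooled S/V, 1/um
ph$truth$true_sa_to_v         # ground truth, same convention

ctrl <- generate_phantom(phantom_spec(grid_shape = c(64, 96, 96),
                                      voxel_pitch = c(8, 8, 8),
                                      n_spheroids = 2,
                                      radius_range = c(110, 150), seed = 1))
disruption_index(global_sa_to_v(seg),
                 global_sa_to_v(segment_nodules(ctrl$volume)))
```

## Known limitations

* The 1.7× rule is applied to linear intensity; if a source pipeline
  thresholds log-compressed data the factor is not transferable (volumes
  carry a `log_scaled` flag and quantitative functions refuse compressed
  input).
* The per-nodule mean rises with apoptotic load, so at high body fractions
  the effective threshold stiffens; recovery stays accurate to ~0.02 up to
  a 0.2 volume fraction under the test conditions, but saturation should be
  expected beyond that.
* Individual spheroids are not tracked across timepoints — wells are the
  unit of analysis, matching the per-well pooling of the slice ledgers.
* The erosion-count distance is not Euclidean; for strongly aspherical
  merged clusters the seeded split is an approximation of a true gradient
  watershed.
* The per-slice despeckle opening removes foreground thinner than its
  kernel. At fine (instrument-scale) pitch this only trims speckle, but at
  coarse demonstration pitches it also suppresses the smallest detached
  fragments, attenuating — though never reordering — the measured
  disruption signal. Quantitative fragment recovery needs voxels small
  relative to the 8–20 µm fragment scale (or `opening_radius = 0`).
```
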