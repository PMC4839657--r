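---
title: "Quantifying colonoid polarization under morphogen gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colonoid polarization under morphogen gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonpol)
```

## The problem

Colonic organoids (colonoids) grown in Matrigel self-organize stem and
transit-amplifying (TA) cells marked by a Sox9EGFP reporter, proliferating
S-phase cells marked by EdU incorporation, and differentiated lineages such
as Muc-2–positive goblet cells. When a linear gradient of the Wnt-pathway
ligands Wnt-3a and/or R-spondin1 is imposed across a single colonoid in a
microfluidic source–sink device, the proliferative compartment polarizes
toward the high-concentration end. `colonpol` provides the computational
side of such an experiment:

1. a physical model of gradient formation and stability in the device
   (`simulate_device()`, `erfc_profile()`, `fit_diffusion_coefficient()`);
2. segmentation of colonoids from fluorescence and brightfield images
   (`segment_colonoids()` and its stages);
3. per-colonoid polarization vectors and positivity calls
   (`sox9_polarization()`, `edu_polarization()`, `positivity()`,
   `measure_colonoids()`);
4. the statistical layer (`mean_vector()`, `holm_sidak()`,
   `condition_ratio()`, `log_qq_check()`, `position_dependence()`);
5. a synthetic-scene generator with exact ground truth (`make_scene()`),
   which is what makes every stage testable without access to raw
   microscopy data.

Conventions: images are matrices with a physical `pixel_size` (µm/px);
`x = 0` is the Matrigel:sink interface and angles are degrees
counter-clockwise from the sink→source axis. All physical thresholds
(minimum area 1000 µm², 20-µm slice, structuring-element radii) are
specified in micrometres and converted through `pixel_size`, never fixed in
pixels; the camera scale is an input because it varies with the objective.

## Gradient model

Entry of a ligand from a loaded source into the gel follows the one-sided
diffusion solution

$$C(x,t) = A + \tfrac12 C_O\,\mathrm{erfc}\!\left(\frac{x}{2\sqrt{Dt}}\right),$$

with $x$ measured from the source interface, a free offset $A$ absorbing
background fluorescence, and $C_O$ the source concentration.
`fit_diffusion_coefficient()` fits all three parameters by
Levenberg–Marquardt least squares over every (position, time) sample and
reports the standard error of $D$. Time-constant inputs are flagged
non-identifiable (with no temporal evolution, $D$ is unconstrained) and
non-convergence is flagged, never silent.

`simulate_device()` models the full device: a 1000-µm channel (1.5 µL)
discretized into 101 finite-volume cells, coupled at both ends to
well-mixed finite reservoirs through half-cell resistances, with reservoir
concentrations reset to their loading values every 24 h. The explicit
flux-form stepper (compiled code) picks its time step from the stability
limit $\Delta t \le \Delta x^2 / (3D)$ with a 0.8 safety factor — the
scheme cannot be run unstably — and conserves mass exactly between refresh
events. The test suite cross-checks it against two independent solutions:
the matrix exponential of the equivalent linear compartment system, and the
erfc profile at early times.

Two geometry details matter and are exposed in `device_geometry()`:

* **Reservoir volume.** The default is 870 × the channel volume
  (≈ 1.3 mL), the device's reservoir wells. A 500-µL media volume is also
  used experimentally and can be configured. The daily drift of the
  gradient scales inversely with this volume: the quasi-steady flux
  through the channel is $D A_c C_O / L \approx 9$ µL·$C_O$ per day, so a
  1.3-mL sink accumulates about 0.7% of $C_O$ between refreshes and a
  500-µL sink about 1.9%.
* **Stability normalization.** `gradient_variation()` reports
  $100\,(\max - \min)$ of concentration over a time window per position,
  normalized either by the per-position time mean (`"position_mean"`) or
  by the source concentration (`"source"`). For a linear gradient the
  per-position mean vanishes toward the sink, so the position-mean form
  diverges there no matter how stable the device is; the source-normalized
  form — drift as a percentage of the full gradient scale — is the
  meaningful stability measure for this geometry and is what the package's
  acceptance script reports for the five-day, daily-refresh scenario
  (24-h establishment, then days 1–5).

## Segmentation

The stages mirror standard practice for organoid fluorescence:

1. **White top-hat** (`tophat_filter()`): image minus its opening with a
   disk of radius 150 µm. The element must be *larger* than a colonoid
   (median area ≈ 13,000 µm², diameter ≈ 130 µm) — an opening with a
   smaller element removes the colonoid itself rather than the background.
   150 µm clears colonoid-scale structure while still tracking
   illumination gradients; it is configurable for other magnifications.
2. **Minimum cross-entropy threshold** (`threshold_min_cross_entropy()`):
   Li's criterion, minimized exhaustively over a 256-bin histogram; the
   tests compare against a brute-force scan over all inter-value midpoints.
3. **Cleaning** (`clean_mask()`): holes filled, objects with area
   *strictly below* 1000 µm² removed (an object of exactly 1000 µm² is
   kept).
4. **Chan–Vese refinement** (`chan_vese_refine()`): the two-phase
   piecewise-constant energy on the brightfield image, initialized from
   the fluorescence mask. Implementation: alternate nearest-class-mean
   reassignment (λ₁ = λ₂ = 1 data term) with majority-filter smoothing
   passes standing in for the curvature penalty (1 pass ≈ weight 0.25);
   converged when the region changes by < 0.1%, otherwise the last
   iterate is returned with a warning flag after 200 sweeps. A
   brightfield image whose phases have indistinguishable means is
   degenerate and returns the initialization, flagged.
5. **Debris and border removal** (`remove_debris()`): an object whose
   matched brightfield region (maximal pixel overlap) is more than 20%
   larger than its fluorescence region is non-cellular or degrading
   material and is dropped. "Larger" compares enclosed **areas** by
   default — robust to contour roughness — with a perimeter comparison
   available via `compare = "perimeter"`. Objects touching the image
   border are always removed, also when no brightfield channel exists;
   fluorescence objects with no brightfield match are kept and reported.

## Polarization metrics

**Rotation-slope (Sox9EGFP).** The EGFP channel is divided pixelwise by
DsRed (`ratio_image()`), normalizing expression by local cell density.
Denominator pixels below 1% of the in-mask median are excluded (a floor
that prevents division blow-ups). The ratio crop is rotated 0–179° in 1°
steps about the bounding-box centroid with nearest-neighbour interpolation;
at each rotation the mean of a 20-µm horizontal slice through the centre is
computed per column (mask pixels only) and fit with a least-squares line
weighted by per-column pixel counts (column means from few pixels are
noisier and sit at high leverage). The rotation with the largest |slope|
gives the direction; |slope|, in ratio units per µm, is the magnitude.
Numerical choices: ties resolve to the smaller rotation angle, and the
1°-grid argmax is refined to sub-degree precision by a local quadratic fit
of |slope|(θ) over ±10° (the curve is s·|cos| near its peak, so the vertex
is well defined). Because slope is per-µm, the magnitude is
device-independent; multiplying both channels by a constant leaves it
unchanged.

**Centroid-offset (EdU).** EdU is punctate (only S-phase cells carry it),
so a slope fit is inappropriate. EdU is divided by Hoechst 33342
(cell-number normalization); the vector from the mask's geometric centroid
to the normalized intensity-weighted centroid gives the angle, and its
length divided by the colonoid's Feret extent along that direction (extreme
projections of mask pixel centres plus one pixel footprint) gives the
magnitude. On centro-symmetric masks this magnitude cannot exceed 0.5, and
an all-intensity-in-the-end-column rectangle of N columns attains exactly
(N−1)/2N.

**Positivity.** After top-hat filtering, a colonoid is positive for a
marker when at least a stated fraction of its pixels exceeds a per-pixel
intensity threshold: fractions 0.25 (Sox9EGFP), 0.10 (Muc-2), 0.25 (EdU),
with ties counting positive. The per-pixel thresholds are empirical
calibration inputs; `calibrate_positivity_threshold()` derives one as a
high quantile (default 99.5%) of negative-control pixels, and
`measure_colonoids()` falls back to the out-of-object pixels of the
analysis image itself.

`measure_colonoids()` also subtracts a flat background estimate (the
out-of-object median) from each fluorescence channel before forming
ratios; without it, a background offset B biases the measured ratio slope
by a factor L/(L+B) for body intensity L.

## Statistics

* `log_qq_check()`: natural-log transform plus the adjusted R² of the
  ordered values against normal quantiles; ≥ 0.91 is treated as adequate
  log-normality for t-tests.
* `holm_sidak()`: step-down Holm–Šidák — reject the i-th smallest p while
  $p_{(i)} \le 1 - (1-\alpha)^{1/(m-i+1)}$; decisions are monotone, never
  fewer than Bonferroni and never more than unadjusted testing.
  `compare_conditions()` feeds it all pairwise two-sided Welch t-tests on
  log values (Welch because group variances differ between conditions;
  colonoids are pooled across devices).
* `mean_vector()` returns two summaries, which differ on dispersed data:
  the **Cartesian resultant** (mean of vector components; opposite vectors
  cancel, so an unpolarized population averages to ≈ 0) with angle and
  magnitude SDs propagated to first order from the component SDs, and the
  **arithmetic mean ± SD of the magnitudes** together with the circular
  mean of the angles — the per-condition summary used for fold ratios.
  With angles dispersed by σ the resultant magnitude shrinks by
  ≈ exp(−σ²/2) relative to the arithmetic mean; both are reported so each
  use picks the right one.
* `condition_ratio()`: gradient-condition mean magnitude over the
  no-gradient baseline mean, to 2 significant figures.
* `position_dependence()`: least-squares line and Pearson correlation of
  colonoid centroid distance from the sink against the x-component of its
  polarization vector; zero position spread is flagged degenerate.

## The synthetic-scene generator

`make_scene()` renders what the measurement stages assume about real data:
elliptical bodies with uniform DsRed (level 200 by default) on a dark
background; an EGFP/DsRed ratio `base + slope·d` (clipped at 0) with exact,
recorded gradient direction; EdU as Gaussian puncta (σ = 2 px) placed
iteratively so the noise-free in-mask weighted centroid lands at the
requested fractional offset; constant Hoechst inside bodies; a Muc-2 cap
over a stated pixel fraction; brightfield with slightly dark bodies and
strongly dark debris whose faint-DsRed footprint is ≈ 36% of its
brightfield footprint (so the 20% rule must fire); additive background plus
an optional linear illumination ramp; and Poisson shot noise (scale 1
count per intensity unit) followed by Gaussian read noise (sd 2) — the
standard CCD model. Defaults give a per-pixel signal-to-noise ratio around
14 on the DsRed body, and body areas near the reported median colonoid
area (≈ 13,000 µm² at 1 µm/px). Identical spec + seed is bit-identical.

Deliberate idealizations — what passing tests do **not** show about real
data: bodies are convex ellipses (no crypt buds or lumens), DsRed is
uniform rather than textured, the EGFP gradient is exactly linear, there
is no optical blur (PSF), no 3-D sectioning effects, no touching
colonoids, and debris is guaranteed separated from bodies by a small
clearance (abutting footprints would merge in brightfield and make the
20%-rule ground truth ambiguous, exactly as overlapping bodies would for
the fluorescence mask). Performance on real images therefore still needs
visual QC; the synthetic oracle validates the arithmetic, not the optics.

## Problem sizes and runtime choices

Test scenes are 220–420 px square at 1 µm/px with 1–4 colonoids; recovery
properties use 20 seeds; the Monte-Carlo fit study uses 20 replicates of a
4 × 51 profile grid; the device simulation covers 6 days at 15-min output
resolution (≈ 1.6 M explicit steps, well under a minute). These sizes keep
the full suite at a few minutes while leaving every estimate comfortably
inside its tolerance.

## Known limitations

* The rotation-slope angle inherits ≈ 1–2° of jitter from the 1° grid and
  shot noise even after sub-degree refinement; at very low SNR the argmax
  can lock onto a noise wiggle.
* The centroid-offset magnitude is biased slightly toward zero on noisy
  images: clipped zero-mean noise spread over the body dilutes the
  weighted centroid (≈ 10% at the default noise level). Noise-free
  recovery is exact to discretization.
* The Chan–Vese surrogate (class-mean reassignment + majority smoothing)
  optimizes the same energy family but is not a level-set evolution;
  contours are pixel-resolution.
* The 1-D device model ignores the third dimension, post arrays,
  convection and any Matrigel binding or partitioning of the ligands.
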