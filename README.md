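# colonpol

Quantifies how the stem/proliferative compartment of colonic organoids
(**colonoids**) polarizes under linear morphogen gradients. Colonoids carry
a ubiquitous DsRed reporter (all cells), a Sox9EGFP reporter
(stem/transit-amplifying cells), Hoechst 33342 nuclear stain, EdU pulse
labeling (S-phase cells) and Muc-2 immunofluorescence (goblet cells), and
are cultured either in multiwell plates or in a microfluidic device whose
1-mm Matrigel channel spans a source and a sink reservoir so that a Wnt-3a
and/or R-spondin1 gradient forms across each colonoid.

The package implements, as tested reusable R functions:

* **Gradient physics** — the one-sided diffusion entry profile
  `C(x,t) = A + ½·C_O·erfc(x / 2√(Dt))` with nonlinear least-squares
  fitting of the diffusion coefficient `D` (`erfc_profile()`,
  `fit_diffusion_coefficient()`), and a 1-D finite-volume simulation of
  the full device — channel plus well-mixed finite reservoirs refreshed
  every 24 h — with a stability metric for the resulting gradient
  (`simulate_device()`, `gradient_variation()`).
* **Segmentation** — top-hat background removal, minimum cross-entropy
  (Li) thresholding, hole filling with a strict 1000-µm² area rule,
  Chan–Vese refinement on brightfield, and removal of non-cellular debris
  (brightfield footprint > 20% larger than the fluorescence footprint) and
  border-touching objects (`segment_colonoids()` and its stages).
* **Polarization metrics** — the rotation-slope Sox9EGFP vector (steepest
  linear gradient of the EGFP/DsRed ratio found by rotating the colonoid
  through 180° and fitting a 20-µm centre slice) and the centroid-offset
  EdU vector (geometric vs intensity-weighted centroid of EdU/Hoechst,
  normalized by colonoid length along the offset direction; bounded by
  0.5), plus marker positivity calls (`sox9_polarization()`,
  `edu_polarization()`, `positivity()`, `measure_colonoids()`).
* **Statistics** — log-transform adequacy via Q-Q adjusted R², Holm–Šidák
  step-down comparisons, compass-vector averaging with first-order
  uncertainty propagation, condition fold-ratios, and
  position-vs-polarization regressions (`log_qq_check()`, `holm_sidak()`,
  `mean_vector()`, `condition_ratio()`, `position_dependence()`).
* **Synthetic scenes** — a generator of multi-channel microscopy scenes
  with exact ground truth (bodies, gradients, EdU offsets, debris, noise)
  so every stage is verifiable without raw image data (`make_scene()`,
  `random_scene_spec()`).

Angles are degrees counter-clockwise from the sink→source axis; `x = 0` is
the Matrigel:sink interface; all physical thresholds are micrometre-based
and converted through the configured pixel size.

## Worked example

Simulate a scene with three polarized colonoids and two debris objects,
segment it, and measure every colonoid:

```r
library(colonpol)

spec   <- random_scene_spec(seed = 42, n_colonoids = 3, n_debris = 2)
scene  <- make_scene(spec)
labels <- segment_colonoids(scene$channels$dsred, scene$channels$brightfield)
records <- measure_colonoids(scene$channels, labels)
records[, c("label", "area_um2", "sox9_angle_deg", "sox9_magnitude",
            "edu_angle_deg", "edu_magnitude")]
#>   label area_um2 sox9_angle_deg sox9_magnitude edu_angle_deg edu_magnitude
#> 1     1    12393            239        0.00999           254         0.209
#> 2     2    13222            354        0.01001           341         0.206
#> 3     3    12002            339        0.01013           352         0.211
```

Both debris objects are rejected by the 20% brightfield rule and exactly
the three colonoids remain. Each row is one colonoid: its DsRed area in
µm² (a cell-number proxy), the direction and strength of its Sox9EGFP
gradient (ratio units per µm; the generator's truth here is slope 0.01 at
angles 237°, 356° and 338° — recovered within ~2° and ~1%), and its EdU
centroid offset as a fraction of colonoid length (truth 0.25; the noisy
estimate reads ~0.21 because in-body shot noise dilutes the weighted
centroid slightly). Condition-level summaries then follow the reporting
conventions:

```r
mv <- mean_vector(records$sox9_angle_deg, records$sox9_magnitude)
mv$mag_mean                      # arithmetic mean magnitude: 0.0100
condition_ratio(0.0049, 0.0006)  # dual-gradient vs no-gradient means -> 8.2
```

And the device model confirms that with 1.3-mL reservoirs refreshed daily,
a 40-kDa analyte gradient, once established, drifts by well under 1% of
the source concentration over five days:

```r
prof <- simulate_device(device_geometry(), D = 7.2e-11, duration_h = 144)
gradient_variation(prof, window = c(24, 144), normalize = "source")
#> [1] 0.7322617
```

Command-line wrappers over the same functions live in
`inst/scripts/colonpol.R`
(`simulate | segment | gradient | run`, e.g.
`Rscript inst/scripts/colonpol.R gradient --days 6 --outdir out/`).

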