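Package: colonpol
Title: Quantifying Stem-Compartment Polarization of Colonoids Under Morphogen Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and gradient-modeling pipeline for colonic organoids
    (colonoids) cultured under linear Wnt-3a / R-spondin1 gradients in a
    source-sink microfluidic device. Provides a synthetic multi-channel
    microscopy scene generator with known ground truth; colonoid segmentation
    from DsRed or Hoechst fluorescence (top-hat background removal, minimum
    cross-entropy thresholding, Chan-Vese brightfield refinement, debris and
    edge-object removal); per-colonoid polarization metrics (rotation-slope
    Sox9EGFP vector and centroid-offset EdU vector); a one-dimensional
    finite-volume model of diffusive gradient formation between refreshed
    reservoirs with erfc-profile fitting of diffusion coefficients; and the
    statistical layer (log/Q-Q adequacy checks, Holm-Sidak step-down
    comparisons, compass-vector aggregation with uncertainty propagation, and
    condition fold-ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
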