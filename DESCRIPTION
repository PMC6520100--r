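Package: penumbra
Title: Peritumoral BOLD Signal Complexity and Connectome Robustness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for distance-dependent effects of focal brain
    tumors on resting-state BOLD fMRI signal complexity and functional
    network robustness. Estimates the Hurst exponent voxelwise with a
    maximal-overlap discrete wavelet transform (Daubechies 8) variance
    regression, builds 2-mm peritumoral annuli with interhemispheric
    mirroring to form homologous-region gradient profiles, derives
    parcel-level connectomes (Pearson, partial, and wavelet correlations)
    with centrality and synthetic-lesioning delta-efficiency metrics, and
    selects among polynomial and exponential distance-gradient models by
    AIC. Includes an exact fractional-Gaussian-noise simulator (circulant
    embedding) and a bilateral phantom-cohort generator with implanted
    quadratic Hurst gradients so every stage is testable without patient
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
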