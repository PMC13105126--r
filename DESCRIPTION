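Package: cnmm
Title: Convolutional Neural Mass Modeling of Hippocampal Spike Density and
    Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-based input-output modeling of spatially discretized
    neural populations ("neural masses") in the hippocampal CA3 subregion.
    Afferent spike-density signals from entorhinal cortex, dentate gyrus and
    neighboring CA3 masses are mapped to a target mass's spike density (or
    layered transmembrane currents) through first-order Volterra kernels
    expanded over discrete orthonormal Laguerre (temporal) and scaled
    Chebyshev (spatial) basis functions. Kernel weights are estimated by
    ridge regression nested inside a particle-swarm search over the six
    structural metaparameters. Includes a grid-cell exploration simulator
    (hexagonal rate maps, inhomogeneous Poisson spiking), spike-density
    preprocessing (conduction delays, 2-ms binning, standardization,
    Gaussian smoothing), a teacher-model generator for recovery benchmarks,
    a point-source local field potential forward model, and kernel-strength
    and Welch spectral analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
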