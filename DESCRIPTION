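Package: diffrec
Title: Low-Dose Diffraction Recognition Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential Bayesian recognition of structural hypotheses from
    individual scattered-particle detections at extremely low radiation dose.
    Far-field diffraction patterns of candidate objects are reduced to shift-
    and rotation-invariant one-dimensional radial probability density
    functions; each detected photon or electron then updates the posterior
    probability over the hypothesis set until a confidence threshold is
    reached. Includes the forward simulators needed to generate and validate
    such patterns (optical Fraunhofer diffraction of 2D objects, coherent
    X-ray scattering from atomic structures with Cromer-Mann form factors,
    and atom-by-atom multi-slice electron scattering with angular-spectrum
    propagation), Gaussian noise models with constant or q-dependent
    signal-to-noise ratio, seeded Monte-Carlo detection sampling, ensemble
    recognition experiments with particles-to-threshold statistics and dose
    accounting, and synthetic glyph/structure generators for self-contained
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    bio3d,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
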