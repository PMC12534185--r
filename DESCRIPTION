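Package: dnamoire
Title: Geometry, Nucleation and Fourier Analysis of Seeded DNA Moire Superlattices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models seeded growth of twisted DNA single-stranded-tile (SST)
    superlattices. Provides geometric models of twisted DNA origami seeds
    (cross-sections, segment heights, twist registry, gradient faces),
    generators and reciprocal-space descriptors for square, kagome and
    honeycomb sublattices, closed-form moire relations for uniform and
    gradient stacks, a classical-nucleation-theory wetting model of seeded
    versus homogeneous nucleation, a stochastic (Gillespie) seeded-growth
    simulator, a synthetic micrograph renderer with ground truth, and an
    FFT analysis stage that recovers twist angles, lattice constants and
    moire periodicities from images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    withr,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
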