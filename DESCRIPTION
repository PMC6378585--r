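Package: parastorm
Title: Parallel Single-Molecule Localization Microscopy Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for single-molecule localization
    microscopy (SMLM/dSTORM) built around frame-parallel processing.
    Provides iterative Gaussian point-spread-function fitting (weighted
    least squares and Poisson maximum likelihood), non-iterative
    phasor-based localization, astigmatic 3D calibration and z lookup,
    interleaved frame scheduling across a local process pool with a
    frame-order-preserving merge, automated postprocessing (physical
    validity filters, intercentile sigma filter, cross-correlation drift
    correction, consecutive-frame merging) and super-resolution rendering
    (histogram, average shifted histogram, Gaussian, and z colour-coded
    projections). Includes a synthetic dSTORM movie simulator with ground
    truth for validation, TIFF/OME-TIFF movie access with strided frame
    reading, and ThunderSTORM-compatible CSV localization tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    parallel,
    tiff,
    png,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'calibrate.R'
    'localize.R'
    'postprocess.R'
    'render.R'
    'io-table.R'
    'parallel.R'
    'pipeline.R'
    'cli.R'
    'detect.R'
    'io-movie.R'
    'utils.R'
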