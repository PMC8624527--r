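Package: pwasoft
Title: Piecewise-Affine Multi-Model Soft Sensors for Batch Bioprocesses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of piecewise-affine ARX (PWARX) multi-models for
    soft sensing of hard-to-measure variables (biomass, product concentration)
    in batch fermentation processes. Model order is selected by the false
    nearest neighbor method with Cao's E/E0 statistics; the number of local
    models and their parameters are optimized jointly by a particle swarm
    optimizer with an iteration-dependent compression factor; dividing
    hyperplanes between adjacent local-model regions are learned by a least
    squares support vector machine. Includes one-step-ahead prediction,
    MAPE/RMSE evaluation against a global affine baseline, synthetic PWARX and
    mechanistic fermentation data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
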