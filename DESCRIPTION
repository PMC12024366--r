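Package: coproFTIR
Title: ATR-FTIR Chemometrics for Hyaenid Coprolite Identification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies mineral and organic infrared band variables from
    ATR-FTIR absorbance spectra of carnivore coprolites, selects a
    parsimonious variable set by a three-step correlation/PCA screening,
    builds per-species convex-hull domains in principal-component space,
    and classifies unknown samples against a fitted reference. Includes a
    synthetic spectrum generator (Gaussian/Lorentzian band mixtures of
    bioapatite, calcite, aragonite, protein, lipid, chitin and keratin
    components) with full ground truth, JCAMP-DX and CSV spectrum I/O,
    rubberband and asymmetric-least-squares baseline correction, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectra-io.R'
    'preprocess.R'
    'band-features.R'
    'chemometrics.R'
    'classify.R'
    'synthetic.R'
    'pipeline.R'
    'utils-geometry.R'
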