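Package: calcphase
Title: Phase Identification and Elastic Moduli of Biogenic Calcium
    Carbonate from Powder XRD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the crystal phase of biogenic calcium carbonate
    from a powder X-ray diffractogram by simulating candidate patterns
    from crystal structures (Cu K-alpha, pseudo-Voigt profiles,
    Lorentz-polarization correction), fitting smooth spectral models to
    the normalized experimental and simulated spectra, and ranking
    candidates by mean absolute error divided by a Boltzmann formation
    probability derived from per-atom formation energies.  Converts
    single-crystal elastic constants of the identified hexagonal or
    trigonal phase into polycrystalline bulk, shear and Young's moduli
    and Poisson's ratio via Voigt-Reuss-Hill averaging, with a
    Poisson-ratio ductility classification.  Includes a transcribed
    candidate catalog of calcium carbonate polymorphs, a scoped CIF
    reader/writer, synthetic fixture generators (reference structures,
    noisy diffractograms, random Born-stable elastic tensors), and the
    assay arithmetic used in biocement characterization (precipitate
    weight, compressive-strength gain).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
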