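Package: fracRheo
Title: Fractional Kelvin-Voigt Analysis of Biological Hydrogel Rheology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative rheological characterisation of soft
    biological hydrogels such as mucin gels. Provides validated containers
    for oscillatory frequency sweeps, amplitude sweeps and steady-shear flow
    curves; forward evaluation of spring, dashpot, spring-pot and fractional
    Kelvin-Voigt models; simultaneous log-residual fitting of storage and
    loss moduli with a configurable frequency cutoff; power-law scaling
    analysis of concentration and additive series; Herschel-Bulkley yield
    stress estimation; linear-viscoelastic-region detection; and quantitative
    pore morphometry of calibrated electron micrographs (Gaussian smoothing,
    Otsu binarisation, edge-excluded particle labelling and Feret diameters).
    Seeded synthetic-data generators with stored ground truth make every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    minpack.lm,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'fractional-models.R'
    'synthetic-data.R'
    'pore-morphometry.R'
    'scaling-analysis.R'
    'model-fitting.R'
    'rheology-io.R'
    'cli.R'
    'fracRheo-package.R'
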