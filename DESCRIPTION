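Package: nucleostrain
Title: Chromatin Displacement and Strain Mapping from Thermally Stimulated Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probe-free analysis of intra-nuclear chromatin deformation from
    fluorescence time-lapse stacks. Converts temperature-sensitive dye
    intensities to temperature profiles and gradients, computes dense
    displacement fields against the undeformed reference frame by multi-pass
    particle image velocimetry, derives hydrostatic and shear strain maps,
    segments chromatin-density compartments, nucleoli and perinucleolar
    shells, fits Kelvin-Voigt viscoelastic parameters to creep/recovery
    dynamics, and produces per-compartment statistics. Includes a synthetic
    phantom generator with exact analytic ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
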