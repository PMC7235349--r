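Package: irsh
Title: Infrared Spectral Histology of Paraffin-Embedded Tissue Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free infrared spectral histology (IRSH) of FFPE tissue
    sections from hyperspectral mid-infrared absorbance images. Provides
    EMSC-based digital dewaxing (per-pixel removal of paraffin interference,
    polynomial baseline and section-thickness scaling), common K-means
    segmentation across images so cluster identities are comparable between
    animal groups, cluster-abundance quantification with two-group Student
    t-tests and fold changes, and pixel-wise Pearson correlation mapping
    against a reference spectrum such as type I collagen. Ships a seeded
    synthetic skin-phantom generator (layered anatomy with hair bulbs,
    paraffin contamination, baseline drift and thickness variation) so the
    whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    rhdf5,
    png,
    yaml,
    clue
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
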