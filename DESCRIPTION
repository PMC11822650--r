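Package: synspread
Title: Quantification of Reporter-Based Alpha-Synuclein Cell-to-Cell Spread Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for dual- and triple-reporter assays of
    neuron-to-neuron alpha-synuclein transfer. Segments neuronal cell bodies from a
    morphology channel with local-mean adaptive thresholding, measures per-cell
    background-subtracted reporter intensities, calibrates positivity thresholds from
    control populations, gates cells into donor/recipient/untransduced classes in
    cultures and brain-section mosaics, scores aggregation puncta and annexin-V
    scramblase indices, measures neurite morphometry from skeletons, and summarises
    spread metrics with the associated group statistics (t-test, one-way ANOVA with
    Tukey HSD, delta-delta-Ct). Includes a seeded synthetic multi-channel microscopy
    generator with per-cell ground truth used as the oracle for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
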