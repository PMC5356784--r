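Package: dropletCNV
Title: Droplet Digital PCR Copy-Number Quantification and Duplication Calling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Poisson partition statistics for duplex droplet digital PCR
    (ddPCR): per-channel template concentration estimation with Poisson-based
    95% confidence intervals, replicate-well merging, copy-number-variation
    (CNV) estimation with propagated CNVmin/CNVmax bounds, and a
    dual-threshold rule for calling FGFR1 tyrosine-kinase-domain internal
    tandem duplications from FFPE material. Includes a seeded synthetic
    droplet-count generator with known ground truth (duplicated-cell
    fraction, concentrations), cohort-level summaries and association tests
    for a 36-sample low-grade neuroepithelial tumor series, and CSV/CLI
    plumbing for an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, ddPCR, StatisticalMethod, Software
RoxygenNote: 7.3.3
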