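Package: acquant
Title: Quantification of Anchor-Cell Polarity, Alignment and Vulval
    Induction in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying vulval induction
    in Caenorhabditis elegans from fluorescence image stacks: dorso-ventral
    and anterior-posterior polarity indices of a ligand reporter in the
    anchor cell (AC) from summed z-projections, the AC-to-P6.p alignment
    index R, ERK kinase-translocation-reporter (KTR) nuclear red/green
    activity ratios per vulval precursor cell, and vulval induction
    statistics with bootstrap confidence intervals. A synthetic-data
    generator produces image stacks, annotated animals and fate-pattern
    cohorts with known ground truth so every stage is testable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
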