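Package: mitoquant
Title: Quantitative Workflows for Mitochondrial ncRNA Biology in the Lung
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tidy re-implementations of the quantitative procedures used to
    characterise a mitochondrial-DNA-encoded small non-coding RNA in alveolar
    epithelial type II cells: grid-overlay mean alveolar chord-length
    morphometry on binarised parenchyma masks, per-cell in situ hybridisation
    dot counting with 4-tier semi-quantitative scoring, fluorescence linescan
    extraction and overlap classification, [U-13C]glucose mass-isotopomer
    enrichment and metabolic flux calculation, extracellular-flux (mito stress
    test) parameter derivation, small-RNA read mapping to a circular
    mitochondrial reference with best-hit filtering and alignment-length
    tabulation, and 2^-ddCt relative quantification. Seeded synthetic-data
    generators with recorded ground truth make every stage testable without
    raw microscopy, spectrometry, or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    readr,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
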