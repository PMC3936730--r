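Package: nomeclone
Title: Clone-Based NOMe-seq Accessibility Footprinting, Bisulfite
    Methylation Mapping and qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-molecule chromatin accessibility analysis for
    amplicon-scale NOMe-seq (GpC methyltransferase footprinting read out
    by bisulfite clone sequencing): cytosine context classification
    (GCH/HCG/GCG/CH), bisulfite-aware clone alignment and per-site
    calling with clone QC, per-site inaccessibility statistics with
    100-bp windowed profiles, chi-square and mid-p exact condition
    comparisons, nucleosome-sized footprint and nucleosome-depleted
    region detection, endogenous CpG methylation lollipop maps with
    CpG-island scanning, and ChIP/FAIRE/RT qPCR quantification
    (percent-of-input, fold enrichment, delta-delta-Ct). Includes a
    seeded synthetic-data generator that emulates cell-state mixtures of
    nucleosome-occupied and depleted molecules with configurable enzyme
    efficiency, bisulfite conversion and sequencing error, so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
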