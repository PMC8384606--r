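Package: exoscan
Title: Donor Introgression Scanning and Phenomic Analysis for Hexaploid
    Wheat Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies wild-relative and synthetic-donor
    introgressions in hexaploid wheat panels from de novo SNP calls.
    Implements depth-conditioned homozygous-reference call designation,
    varietal-SNP masking, missing-data and minor-allele-frequency locus
    filtering, identity-by-state matching against donor variant sets,
    500-kbp bin counting with a 5-fold elite-baseline classification
    rule, segment merging and donor-fraction accounting, subpopulation
    SNP-density contrasts, windowed Hudson Fst with a pseudo-split
    control, and the Evanno delta-K statistic. Also provides a leaf
    hyperspectral index registry (NDVI-family, pigment, senescence and
    water indices) and broad-sense heritability estimation from
    multi-environment trait tables, plus a seeded synthetic-data
    generator emulating elite and exotic wheat panel structure so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
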