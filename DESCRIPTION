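Package: morphosim
Title: Morphometric Similarity Networks and Imaging Transcriptomics of
    Chronic Pain Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-subject cortical morphometric-similarity (MS)
    networks from regional structural features, estimates covariate-adjusted
    case-control maps of regional MS, extracts a cross-condition principal
    component of MS remodelling, relates it to regional gene expression with
    partial least squares (permutation and bootstrap inference), assesses
    spatial correspondence with spherical spin-test nulls, and tests gene-set
    overlap enrichment with Fisher's exact test. A synthetic-data module
    generates cohorts, donor-level expression tables and gene sets with known
    planted effects so that every stage of the pipeline is verifiable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
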