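Package: mirTarScan
Title: Seed-Match microRNA Target Site Scanning and Metabolic Cohort Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects canonical microRNA seed-match target sites (8mer,
    7mer-m8, 7mer-A1, 6mer and offset-6mer) in 3'-UTR sequences and
    annotates each site with binding-context features (local AU content,
    3'-supplementary pairing, position within the UTR, proximity to the
    stop codon, cooperative neighbouring sites). Also provides
    cross-species seed-family conservation analysis, a validated-interaction
    store, a cohort association screen (linear and logistic regression of
    metabolic traits on miRNA log2 expression with confounder exclusion and
    Benjamini-Hochberg FDR), delta-delta-Ct qPCR quantification with a
    3-SD outlier rule, and seeded synthetic-data generators for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
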