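Package: minimalgut
Title: Design and Analysis of Minimal Gut Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing defined minimal gut microbial
    communities: core-microbiota occupancy screening of taxon abundance
    tables, probabilistic (hypergeometric) pairwise species co-occurrence,
    consortium coverage of core KEGG ortholog (KO) functions, quantitative
    microbiota profiling from amplicon counts via 16S rRNA gene copy-number
    correction and qPCR scaling, reverse-ecology seed-set detection with
    pairwise competition and complementarity indices on genome-based or
    expression-based KO sets, and gut metabolic module (GMM) scoring of
    per-species transcriptomes. A synthetic-data generator produces every
    input class with known ground truth so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
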