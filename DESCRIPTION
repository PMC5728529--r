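Package: mucinscan
Title: Multi-Evidence Identification of Gel-Forming Mucin Genes and qPCR
    Stress-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate secreted gel-forming mucin genes in a genome
    by combining three layers of evidence: annotation keywords, transcription
    (FPKM across tissues), and protein domain architecture (a minimum
    VWD-C8-TIL cassette plus compositionally defined PTS regions found by a
    sliding-window scan). Extracts positionally labelled VWD domains and builds
    a neighbor-joining phylogeny with bootstrap support. Implements the qPCR
    relative-quantification chain used in stress-response experiments:
    technical-duplicate quality control, primer efficiency from dilution
    series, reference-gene stability ranking (geNorm-M, BestKeeper,
    NormFinder-style and comparative delta-Ct measures), delta-Ct
    normalisation, tissue profile matrices and log2 fold changes with
    linear-model testing. A synthetic-data generator with known ground truth
    makes every stage verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
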