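Package: cgckit
Title: CAZyme Gene Cluster Detection and Glycan Substrate Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CAZyme gene clusters (CGCs) in annotated microbial
    genomes and metagenome-assembled genomes, and predicts the glycan
    substrate of each cluster by two complementary approaches: homology
    mapping against a database of experimentally characterized
    polysaccharide utilization loci (PULs) scored by summed pairwise
    bit scores, and majority voting over per-CAZyme substrate
    annotations derived from a CAZyme subfamily to EC number to
    substrate mapping table. Includes a multi-tool CAZyme consensus
    rule, per-gene signature classification (CAZyme, transporter,
    transcription factor, signal transduction protein), agreement and
    summary statistics across the two substrate-prediction approaches,
    a deterministic synthetic fixture generator for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rtracklayer,
    Biostrings,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
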