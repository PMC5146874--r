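Package: ckreg
Title: Promoter Motif Enrichment and Cross-Platform Validation for
    Cytokinin Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hormone-responsive transcriptomes in plants,
    built around the question of whether a transcription factor's binding
    motifs are over- or under-represented in the promoters of differentially
    expressed genes. Provides strand-aware promoter window extraction from a
    genome and annotation, exact k-mer motif scanning (including degenerate
    patterns and protein-binding-microarray 8-mer lists), and a Monte-Carlo
    resampling enrichment test with a closed-form hypergeometric cross-check.
    Also implements NanoString nCounter normalization (negative-control
    background, positive-control standard-curve scaling, reference genes) with
    not-detected propagation into log2 fold changes, cross-platform
    fold-change concordance and gene-set overlap/direction analyses, RPKM and
    expression summaries, and seeded synthetic-data generators (toy genomes
    with planted motifs, simulated nCounter panels, correlated fold-change
    pairs) so every stage can be tested against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
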