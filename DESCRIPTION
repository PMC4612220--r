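Package: syntenr
Title: Significance-Tested Syntenic Clusters from Exon-Level Protein Homology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects statistically significant syntenic clusters between two
    annotated genomes at the translated-exon level. Exons are translated to
    peptides and compared by a bi-directional protein aligner; reciprocal hits
    are merged, clustered per chromosome pair by single-linkage on a genomic
    hit distance, and every candidate cluster is scored by a coverage- and
    significance-aware score penalised for unaccounted exons. Cluster
    significance is assessed against a permutation null with early stopping,
    or a normal approximation for large clusters, and the dendrogram is cut
    greedily under a dynamically grown Bonferroni correction. Results are
    exported as tables, BED files and Circos-ready data files. A synthetic
    genome-pair generator with planted syntenic blocks, rearrangements and
    duplications supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
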