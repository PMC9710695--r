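Package: mspa
Title: Multiple Spliced Alignment of Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multiple spliced alignments (MSpAs) of a gene family by
    greedily assembling pairwise spliced alignments (PSpAs) of coding
    sequences (CDSs) against gene sequences. A spliced alignment graph links
    aligned exon segments across genes; its connected components, split at
    low-confidence edges wherever they would mix non-overlapping segments of
    one sequence, become candidate multiblocks that are chained into a valid
    MSpA. From the MSpA the package derives multiple CDS alignments, CDS
    splicing-orthology groups (identical multiblock membership with segment
    lengths congruent modulo 3) and homology-predicted gene models, with
    evaluation metrics (alignment precision/recall/F-score, Rand index,
    prediction scores) and a small gene-family simulator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    ape,
    withr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
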