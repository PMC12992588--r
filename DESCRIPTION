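Package: stallscan
Title: Proteome-Scale Discovery of Translation-Impeding RAPP-Like Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the proteome-scale analysis of translation-impeding
    tetrapeptide motifs in bacteria. Computes a composition-normalized
    k-mer frequency-bias statistic over sliding windows of predicted
    proteomes, aggregates it by phylum or class (with capped per-clade
    subsampling and ECDF summaries) and ranks globally underrepresented
    patterns; performs a motif census with a small-protein filter,
    distance-to-C-terminus distributions and a pluggable secretory /
    transmembrane / cytosolic localization classifier; pairs
    motif-encoding upstream ORFs with their same-strand downstream genes
    from GFF3 annotation and tests per-annotation-group enrichment with
    an exact hypergeometric Fisher test and Benjamini-Hochberg
    correction; and generates synthetic proteomes and annotated toy
    genomes with known planted structure so that every pipeline stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
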