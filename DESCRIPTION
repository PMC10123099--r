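Package: splicedown
Title: Downstream Analysis of Differential Alternative Splicing Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for rMATS differential-splicing output.
    Parses and filters JCEC event tables for all five alternative splicing
    types, measures the transcriptome footprint of splicing changes against
    gene expression, characterises event structure against a BED12
    annotation (unannotated skip junctions, multi-exon skipping, intron and
    exon sizes), scores donor and acceptor splice sites with
    maximum-entropy models, reconstructs and translates exon-skipped
    isoforms to classify reading-frame effects, frameshift neopeptides and
    nonsense-mediated decay candidates under the 50-nt rule, and compares
    splicing profiles across experiments with hypergeometric overlap tests
    and clustered p-value matrices. Includes a deterministic synthetic data
    generator producing toy genomes, annotations, event tables and
    expression matrices with a machine-readable truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    pheatmap,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
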