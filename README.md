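# splicedown

Downstream analysis of differential alternative splicing. Callers such
as rMATS turn RNA-seq into tables of significant splicing changes —
often thousands of skipped-exon (SE) and retained-intron (RI) events —
and leave the investigator to work out what they mean. splicedown takes
those tables (JCEC dialect), a BED12 transcript annotation with CDS, a
genome FASTA and a TPM expression table, and answers the questions that
usually follow:

- **Footprint** — what fraction of expressed genes (at minimum TPM
  thresholds) carry significant skipping or retention changes, per
  inclusion-difference sign?
- **Structure** — which skip junctions are absent from the annotation
  (novel splicing)? How many annotated exons does each junction skip
  over? What are the sizes of the exons and introns involved, against
  an annotated-transcriptome baseline?
- **Mechanism** — how strong are the donor (9-mer, 3 exonic + 6
  intronic nt) and acceptor (23-mer, 20 intronic + 3 exonic nt) splice
  sites of each event, scored in bits as a maximum-entropy
  log-likelihood ratio `log2 P_model / P_background`?
- **Consequence** — reconstruct each skipped isoform on its host
  transcript, translate it, classify the frame effect (`frameshift` iff
  removed coding length mod 3 ≠ 0), extract frameshift neopeptides and
  in-frame excised peptides, and call nonsense-mediated decay (NMD)
  candidates by the strict 50-nt rule: a termination codon **> 50 nt**
  upstream of the isoform's final exon–exon junction.
- **Similarity** — compare significant event sets across experiments
  per type and sign with exact upper-tail hypergeometric tests
  (population = all events tested across both experiments), emitting
  p-value and −log10 matrices and average-linkage clustered heatmaps.

A deterministic synthetic-data generator (`generate_fixtures()`) emits
a complete toy input bundle — genome, annotation, event tables,
expression, comparison experiments — with a truth manifest covering
every planted property, so the whole pipeline is testable offline.

## Worked example

```r
library(splicedown)

fx <- generate_fixtures(fixture_spec(1), "fixtures")
events <- read_rmats(fx$paths$se, "SE")
sig    <- filter_significant(events, fdr_threshold = 0.0005)
txs    <- read_bed12(fx$paths$annotation)
idx    <- build_junction_index(txs)
genome <- load_genome(fx$paths$genome)

classify_annotation(sig, idx)$summary
#>       sign total unannotated fraction_unannotated
#> 1 negative    13           3            0.2307692
#> 2 positive     4           0            0.0000000
```

Of the 13 significant increased-skipping events (negative inclusion
difference), 3 use skip junctions not present in the annotation —
novel splicing.

```r
nmd <- run_translate_nmd(sig, txs, genome)
nmd$summary[, c("sign", "n_translatable", "n_frameshift", "n_nmd",
                "fraction_nmd", "n_neopeptides_gt12")]
#>       sign n_translatable n_frameshift n_nmd fraction_nmd n_neopeptides_gt12
#> 1 negative             10            8     6         0.60                  5
#> 2 positive              4            2     1         0.25                  1
```

Ten increased-skipping events land on translatable host transcripts; 8
frameshift, and 6 terminate more than 50 nt upstream of the last
junction — predicted NMD targets (fraction 0.60). Five frameshift
neopeptides are longer than 12 aa, the usual cutoff for neo-epitope
candidates.

```r
expr <- read_expression(fx$paths$expression, n_control = 2)
fraction_expressed(sig, expr, min_tpms = c(1, 3), sign = "negative")$summary
#>   min_tpm     sign expressed_gene_count as_gene_count  fraction
#> 1       1 negative                   35            11 0.3142857
#> 2       3 negative                   29            10 0.3448276
```

At a minimum of 3 TPM in the control condition, 10 of 29 expressed
genes (34%) carry a significant increased-skipping event.

One-command drivers mirror the tool suite: `se_medley()` runs all six
SE analyses, `ri_medley()` the three RI analyses, `batch_medley()` a
whole directory of `<experiment>_SE.MATS.JCEC.txt` files, and
`compare_all()` the cross-experiment overlap analysis. A thin
command-line dispatcher ships at `inst/cli/splicedown.R`.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
conventions and design decisions, including why the shipped
splice-site model tables are synthetic and what that means for score
comparability.

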