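---
title: "Methods: downstream analysis of differential splicing with splicedown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of differential splicing with splicedown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and inputs

splicedown post-processes the output of a differential-splicing caller
(rMATS-style JCEC tables) for the five alternative splicing types —
skipped exon (SE), retained intron (RI), alternative 5'/3' splice site
(A5SS/A3SS) and mutually exclusive exons (MXE) — together with a BED12
transcript annotation carrying CDS spans, an indexed genome FASTA and a
TPM expression table. It does not call splicing events, align reads or
quantify expression; those belong to the upstream tools whose outputs
it consumes.

The JCEC column contract is positional and 1-based: gene symbol in
column 3, chromosome in 4, strand in 5, 0-based half-open coordinates
in columns 6–11 (6–13 for MXE), FDR in column 20 (22 for MXE) and
inclusion-level difference in column 23 (25 for MXE). Line 1 must be a
header. Tables assembled by hand from other callers are accepted when
they respect these positions; `lenient = TRUE` pads missing trailing
columns. All coordinates inside the package are 0-based half-open on
the genomic axis, BED-native.

Significance is a strict `FDR < 0.0005` by default. Strictness at the
boundary is deliberate: a tie at the threshold is excluded. On SE
events a *negative* inclusion difference means increased skipping under
the test condition; on RI a *positive* difference means increased
retention. The parser assumes rMATS sample 1 is the test condition;
`flip_sign` negates the differences for reversed designs. Events with
an inclusion difference of exactly zero belong to neither sign class.

rMATS labels flanking exons "upstream"/"downstream". Whether those
labels are transcript-oriented or genomic-axis-oriented on the minus
strand varies between producers, so `se_view()` re-orders the flanking
pair onto the genomic axis first and derives transcript-oriented labels
from the strand. Downstream modules are therefore correct under either
emission convention.

## Footprint of splicing changes

`fraction_expressed()` reports, per minimum-TPM threshold, the fraction
of expressed genes carrying at least one significant event of the
requested sign. A gene is *expressed* at threshold $t$ when the mean of
its control-condition TPM columns is at least $t$; `all_replicates =
TRUE` switches to requiring every control replicate at or above $t$,
since reasonable pipelines differ on this aggregation. The default
threshold grid is {1, 2, 3, 5} TPM, with 3 TPM the conventional
headline value. Gene matching is exact, case-sensitive symbol equality;
event genes absent from the expression table are reported in a
diagnostics listing and excluded from the fraction rather than silently
dropped. A gene with several events counts once — the footprint is
gene-level.

## Structural characterization

*Unannotated skip junctions.* A skip junction is the interval between
the upstream-exon end and the downstream-exon start. It is annotated
when exactly that interval is an intron (gap between consecutive exons)
of some transcript on the same chromosome and strand. Matching is exact
by default; `fuzz = N` tolerates ±N nt per end for annotations in an
off-by-one dialect.

*Multi-exon skipping.* `count_intervening_exons()` counts annotated
exon loci fully contained in the skip junction. Contained exons are
merged into overlap clusters before counting, so isoform-to-isoform
wobble of one exon's ends still counts one locus; `per_interval = TRUE`
counts distinct intervals instead, because the right convention is
genuinely arguable. A typical single-exon event scores 1 (the skipped
exon itself is an annotated locus). The distribution is summarized in
bins 0/1/2/3/≥4.

*Sizes.* Per event, the five element lengths (upstream exon, upstream
intron, skipped exon, downstream intron, downstream exon; three for RI)
are pure coordinate arithmetic with transcript-oriented labels: on the
minus strand the genomic-left flank is the *downstream* exon. The
annotated-transcriptome baseline enumerates every internal exon of
every multi-exon transcript as a potential skipping configuration
(duplicates collapsed), and every consecutive exon pair as a potential
retention configuration.

## Splice-site scoring

Donor sites are 9-mers (last 3 exonic + first 6 intronic bases),
acceptor sites 23-mers (last 20 intronic + 3 exonic bases), scored in
bits as $\log_2 P_\text{model}(s) / P_\text{background}(s)$. The
scoring machinery follows the classic maximum-entropy decomposition:
near-invariant positions (GT at donor +1/+2, AG at acceptor −2/−1) are
scored by consensus frequency ratios; the 7 variable donor positions by
a joint probability-ratio table over all $4^7$ sequences; the 21
variable acceptor positions by a product/quotient combination of nine
overlapping sub-model tables.

The tables shipped with the package are **synthetic**: they are
expanded from compact position-marginal frequency matrices shaped on
canonical human splice-site composition (the maximum-entropy model
constrained on marginals alone), with a background of A/T 0.27, C/G
0.23. Scores are deterministic, internally consistent, and rank strong
against weak sites as expected — the canonical donor `CAG|GTAAGT`
attains the maximum over all GT-core 9-mers by exhaustive enumeration —
but they are *not numerically comparable* to scores from the published
trained models, and the package says so in its documentation. Users
with access to trained tables can drop them into the documented
plain-text dialect read by `load_models()`. Sites containing ambiguity
codes or falling off the contig are excluded from averages and counted
in a diagnostics column rather than scored.

For an SE event the four sites of the skipping configuration are
scored: upstream exon donor, skipped exon acceptor, skipped exon donor,
downstream exon acceptor — all in transcript orientation. For RI, the
donor and acceptor of the retained intron. Per-sign means, the
negative/positive mean ratio per site role and the annotated baseline
are reported.

## Isoform translation and NMD

For each significant SE event the package looks for *host* transcripts
whose intron chain contains both flanking introns of the inclusion
isoform. When several match, the representative is the one with the
longest CDS, ties broken lexicographically by transcript ID (all
matches are recorded). Junction-based matching was chosen over
requiring the exact skipped exon because flanking introns identify the
inclusion isoform unambiguously; deleting the skipped exon does require
an exact exon match, and hosts failing it are skipped with a flag.

The skipped isoform is the host minus the skipped exon, CDS span
inherited. Translation starts at the first CDS base mapped into isoform
coordinates (a non-ATG start after splicing is flagged but translated;
a CDS start inside the removed exon marks the outcome invalid). The
frame class is `frameshift` exactly when the removed coding length is
not a multiple of 3. Events not overlapping the CDS are classified
`utr5_only`/`utr3_only` and leave the protein unchanged; non-coding
hosts yield `noncoding`.

The NMD rule is the canonical 50-nt rule, applied strictly: the isoform
is a candidate when its translation terminates **more than 50 nt**
upstream of its **final** exon-exon junction, measuring from the last
base of the termination codon. A stop exactly 50 nt upstream, or in the
final exon, is not a candidate. In-frame events that create a junction
stop are thereby tested like any other premature termination. The
reported NMD fraction uses translatable events (hosted, coding host,
CDS start intact) as the denominator, with all counts reported
alongside so either convention can be reconstructed.

Frameshift events additionally yield the *neopeptide*: residues from
the first codon altered by the shift (the codon containing the new
junction) through the residue before the stop, with the count of
neopeptides longer than 12 aa summarized. In-frame events yield the
*excised peptide*: the host-protein residues overlapping the removed
coding interval, emitted in FASTA for conserved-domain searching.

## Cross-experiment comparison

`compare_all()` intersects significant event sets between every pair of
experiments per type and sign (`neg`, `pos`, and their union `total`),
using canonical event keys (type + chromosome + strand + full
coordinate tuple) so identity is geometric, not label- or order-based.
Each overlap of $k$ events between sets of size $K$ and $n$ is scored
with the exact upper-tail hypergeometric probability $P(X \ge k)$,
taking the union of all tested events across the two experiments as the
population $N$ — a deliberately conservative surrogate; an
intersection-based population is a one-line change if a user wants the
sensitivity analysis. p-values are raw by default so the matrices
remain amenable to any multiple-testing treatment downstream.

For display, p is floored at $10^{-300}$ before $-\log_{10}$, the
diagonal records the minimal attainable tail value, and the clustered
heatmap uses average-linkage hierarchical clustering on Euclidean
distances of the $-\log_{10}$ rows with the diagonal masked to zero —
recorded in the output metadata, since "default clustering" is not a
specification.

## The synthetic data generator

`generate_fixtures()` emits a complete input bundle — genome FASTA,
BED12 annotation with CDS, JCEC tables for all five types, expression
table, a directory of comparison experiments — plus a truth manifest
covering every planted property. It is the package's test bed and a
worked example; it is not a simulator of realistic human gene
structure.

Design choices, fixed once: two contigs of roughly 60–100 kb; 24
skipped-exon event genes (13 significant increased-skipping events —
ten single-skip forming the NMD battery of 6 frameshift-NMD with
termination offsets {51, 75, 90, 120, 200, 300} nt, 2 frameshift
non-NMD at the boundary offsets {10, 50} nt, 2 in-frame, with 3 of the
13 junctions left unannotated — plus 3 multi-skip events with 2/3/4
intervening exons), 4 significant increased-inclusion events, 7
non-significant events including one at exactly the FDR threshold; 7
retained-intron genes; 12 background genes; 6 comparison experiments in
two planted similarity groups of three over a shared 60-event
population. Coding sequence outside deliberate signals is drawn from
the T-free alphabet {A,C,G}, which cannot form a stop codon in any
reading frame; premature stops are injected at exact planned positions,
which makes frame classes and junction–stop distances hold by
construction on both strands. Every intron is a real GT..AG intron with
donor/acceptor windows planted strong (model consensus), weak
(low-frequency choices) or sampled from the model marginals. The
generator re-translates every planted isoform at the string level — a
code path independent of the genomic pipeline it later validates — and
refuses to write fixtures that fail their own truth.

What passing fixture tests shows: the coordinate arithmetic, strand
handling, frame accounting, NMD rule, set algebra and scoring machinery
are exact on inputs whose truth is known. What it does not show:
behavior on the messiness of real annotations (overlapping genes,
micro-exons, non-canonical splice sites, selenoproteins, chromosome
naming surprises beyond the chr/bare dialects), or calibration of the
synthetic site models against biological site strength.

## Numerical and degenerate-input choices

Duplicate events (identical key) keep the smallest FDR with a warning.
Duplicate expression rows keep the largest control mean. Empty
significant sets produce zero-count summaries with `NA` fractions, not
errors. Fractions are undefined (`NA`) when their denominator is zero.
The hypergeometric tail is delegated to R's `phyper` (log-space
internally); the test suite checks it against brute-force enumeration
for every configuration with $N \le 20$. Scoring is a pure function;
the suite checks table-lookup scoring against an independent
marginal-sum oracle to below $10^{-9}$ bits and across a write/load
round trip of the table files.

Problem sizes in the shipped tests — the fixture scale above, a
1,000-sequence scoring panel, the exhaustive $4^7$ donor enumeration
and the exhaustive $N \le 20$ hypergeometric grid — were chosen so the
whole suite completes in a few minutes on one CPU while still
exercising every planted truth exactly.

## Known limitations

Only BED12 is accepted for annotation (no GTF/GFF conversion);
RI events are not translated; branch points are not scored; there is no
multi-process dispatch. The shipped splice-site models are synthetic
(above). Overlap comparison requires coordinates from the same genome
build — there is no fuzzy cross-build matching.
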