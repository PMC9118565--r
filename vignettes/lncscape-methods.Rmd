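---
title: "Identifying and characterizing plant lncRNAs with lncscape"
author: "lncscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing plant lncRNAs with lncscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscape)
```

## Scope and model

`lncscape` takes an assembled, strand-resolved transcriptome (GTF), a
coding-gene annotation with CDS/UTR structure (GFF3), and a set of
companion tracks — repeats, conservation scores, variants, ChIP-seq peaks,
expression — and produces the two-class lncRNA annotation (lincRNA /
lncNAT) plus the molecular, TE, conservation and expression statistics
that characterize it. Upstream steps that have mature dedicated tools
(read mapping, transcript assembly, coding-potential prediction, repeat
masking, whole-genome alignment, peak calling, BLAST) are consumed as
their standard output formats, never re-implemented: the package's
contribution is the strand-aware classification and the statistics
downstream of it.

## Identification and classification

A candidate transcript is retained when its spliced length exceeds 200 nt,
both coding-potential predictors call it noncoding, it has no
protein/domain/RNA-family database homolog, and its FPKM exceeds 0.5
(single-exon) or 0.1 (multi-exon). All thresholds are strict inequalities,
all four criteria are evaluated for every transcript, and every failed
criterion is recorded — a transcript failing on length and expression
reports both.

The expression criterion needs one number per transcript from a
transcripts × tissues matrix; we use the maximum FPKM across tissues, on
the grounds that a transcript convincingly expressed in one tissue is
real even if silent elsewhere. This is configurable.

Survivors are classified in a fixed decision order:

1. **lncNAT** — at least 1 bp of exon–exon overlap with a coding gene on
   the opposite strand (the threshold is a parameter; 1 bp is the most
   inclusive reading of "antisense to one or more exons").
2. **sense_overlap_excluded** — otherwise, any exon–exon overlap with a
   same-strand coding exon. Such transcripts may be unannotated isoforms
   or assembly fragments of the coding gene; they are excluded from both
   lncRNA classes but reported, not dropped.
3. **intronic** — otherwise, a span still touching a gene span means the
   transcript lies wholly within introns. The two-class scheme has no home
   for these, so they are surfaced as their own category.
4. **lincRNA** — no contact with any gene. No distance buffer is applied
   by default (a `gene_buffer` parameter exists for stricter intergenic
   definitions).

Putting the antisense test first means a transcript overlapping gene A
antisense and gene B sense is called lncNAT; with loci of ordinary density
this situation is vanishingly rare, and the order is stated here because
it is the one the per-base oracle in the test suite mirrors.

Overlap arithmetic is bp-exact: both interval sets are unioned before
summation so a base shared by two exons is never counted twice.

### Coordinates

All internal coordinates are 1-based closed — the GRanges convention every
interval operation in the R/Bioconductor ecosystem shares. The 0-based
formats (BED, bedGraph, narrowPeak) are converted at the I/O boundary by
`rtracklayer`. Using the ecosystem's single native convention, rather than
inventing an internal 0-based layer, removes a whole conversion surface
where off-by-one errors breed.

## Molecular features

Per class we report length (spliced), exon number, splicing ratio, GC,
and SNP density. *Splicing ratio* is the fraction of transcripts with at
least two exons; junction-read-based definitions would need the raw reads,
which are out of scope. *SNP density* divides the count of retained
variants inside the class's exon union by the union length in kb — the
union denominator prevents overlapping transcripts from double-counting
both variants and bases. Variant retention is quality > 10 and depth > 5
(strict), single-nucleotide records only, with multi-library records
merged by position; "quality" is read from the VCF QUAL column (the
per-genotype GQ is an alternative some callers prefer; the threshold
source is configurable). GC excludes ambiguous bases from the denominator.

Intergenic control intervals are drawn uniformly from the complement of
gene spans with lengths resampled from the lincRNA length distribution, so
GC and conservation comparisons against transcribed classes are not
confounded by length.

Splice-site profiles tabulate base composition in a window of `flank`
exonic plus `flank` intronic bases around each donor and acceptor;
minus-strand junctions are reverse-complemented so every junction reads
5'→3' and the canonical GT/AG dinucleotides sit at intronic positions
+1/+2 and −2/−1.

## TE origination

A lncRNA is *TE-derived in its exons* when exon sequence shares at least
5 bp with repeat sequence; gene-body overlap uses the whole span. For the
coding-gene comparison the "exonic" variant uses CDS, which is the
conservative choice (UTRs tolerate TE insertions much as lncRNAs do; a
UTR-inclusive mode exists). Class I vs Class II composition is computed on
TE *bases* inside each region set; repeats that are neither
(simple/low-complexity and friends) are excluded from the two-class
fractions and reported separately. The RepeatMasker vocabulary is mapped
by class/family prefix — LINE/SINE/LTR/Retroposon → I,
DNA/RC/Helitron/TIR/MITE → II — and unknown families become `other` with
a warning, never an error.

The annotation formats carry no promoter, so one is defined: 1 kb
immediately upstream of the TSS on the transcript's strand, clipped at
chromosome ends — the common convention for compact plant genomes. A
promoter is *TE-derived* when a TE covers the TSS base itself (the
biologically decisive case: the transcript starts inside the TE) **or**
TEs cover at least half the window. Both clauses and both parameters are
configurable; with the TSS clause disabled the TE-derived fraction is
monotone in the coverage threshold, which the tests exploit.

A TF binding site *originates from a TE* when the peak summit falls inside
the intersection of a promoter with a TE; narrowPeak summits are used
directly and peaks without one fall back to the interval midpoint (logged).

## Conservation

Per-transcript conservation is the mean per-base score over the spliced
(exonic) sequence: the statistic describes the transcript, so introns
never contribute, and bases missing from the track are excluded from both
numerator and denominator rather than imputed as zero. The *conserved
patch* statistic slides a 12-bp window one base at a time along the
spliced coordinate (windows may bridge exon junctions); a transcript has a
conserved patch when some window mean exceeds 0.6 while the whole-
transcript mean stays below 0.3 — a conserved island in an otherwise
unconstrained transcript. Both inequalities are strict: a uniform-0.6
track yields no patch, and a uniformly conserved transcript is not a
"patch" case however high its windows score. Windows containing missing
bases are disqualified rather than imputed. Transcripts shorter than the
window are flagged and never patch-positive.

Cross-species homology consumes precomputed blastn tabular hits; entry
(a, b) of the matrix is the fraction of species a's lincRNAs with at least
one hit in species b passing e-value ≤ 1e-5 and alignment length ≥ 50 bp.
The tools print no thresholds for this step, so these common blastn
screening defaults are used, recorded in the output metadata, and
configurable; matrix entries are monotone in both.

## Tissue specificity and network candidates

The Jensen–Shannon specificity of an expression vector x is computed as
`max_t [1 − sqrt(JSD(p, e_t))]` with p = x/Σx, e_t the indicator
distribution of tissue t, and the divergence in bits (0·log0 := 0). A
transcript expressed in exactly one tissue scores exactly 1, and the score
is invariant to rescaling. One caveat is worth stating rather than
patching: a perfectly uniform vector does **not** score 0 (≈ 0.404 over
five tissues); 0 is the infimum as expression spreads over ever more
tissues. Scores are computed on raw FPKM by default with a
log10(FPKM + 1) option, since the upstream convention is not fixed.
All-zero vectors are undefined and flagged, not scored 0.

TS (tissue-specific) transcripts are those with JS ≥ 0.9 — inclusive, so
a transcript exactly at the threshold is TS — and their TS tissue is the
argmax tissue, ties broken by column order.

Network candidate selection needs an "expressed in a tissue" call, for
which FPKM ≥ 0.1 is used (configurable). The lncNAT rule ranks maximum
FPKM within the lncNATs that already pass the 1–2-tissue clause (a
whole-class ranking is available by flag); the lincRNA and mRNA rules use
strict `max FPKM > 1`.

## The synthetic-data generator

`generate_dataset()` lays out a single 300-kb chromosome with
non-overlapping loci: 25 coding genes with exon/intron structure,
CDS/UTRs and canonical GT–AG splice sites; 20 lincRNAs at least 1 kb from
any gene; 12 lncNATs planted antisense over coding exons; plus decoys for
every boundary class (length 199/200, coding- and homology-flagged,
under-expressed single- and multi-exon, same-strand overlapping,
intron-contained). Single-exon fractions follow the structure typical of
plant lncRNA landscapes (65% lincRNA, 82% lncNAT, 22% mRNA). Five tissues
(root, stem, leaf, flower, seed) carry planted expression profiles —
single-tissue (TS), exact two-tissue, and uniform — and planted SNP
densities (8/7/3 per kb for lincRNA/lncNAT/CDS) reflect the elevated
mutation tolerance of noncoding sequence. The conservation track is
piecewise-constant with a planted gradient (CDS 0.75 > UTR 0.40 > lncNAT
0.45 > lincRNA 0.08 > intergenic 0.03) and 12-bp patches at 0.9 inside
six lincRNAs; GC follows a parallel gradient. TEs are planted three ways:
inside lincRNA exons (20–120 bp), across TSSs (TE-derived promoters, with
TF peak summits planted inside four of them), and as background in a
region kept clear of every promoter, so the planted per-transcript truth
is exact by construction. Homology hit tables are planted per species pair
with known passing fractions.

Truth is computed by generator-side per-base masks — an arithmetic path
independent of the interval machinery the pipeline uses — so every
module's output is scored exactly (zero tolerance on labels). Each
component draws from its own derived substream of the seed, so adding a
component never perturbs the others, and identical seeds give
byte-identical bundles.

What the generator does **not** emulate: assembly noise and fragmented
transcripts, overlapping gene models and isoforms, realistic repeat
sequence content (TEs are coordinates with class labels), continuous
conservation tracks, or read-level variability. Passing tests therefore
demonstrate correctness of the arithmetic and the threshold conventions on
clean, planted structure — not robustness to messy assemblies.

`plant_boundary_cases()` emits a second, tiny bundle whose transcripts sit
exactly at and just beside every printed threshold (length 199/200/201;
FPKM 0.5 and 0.1 at and above; TE overlap 4/5 bp; window means
0.55/0.60/0.65; JS just below, at, and above 0.9, the at-threshold vector
solved numerically), with the expected outcome of each case recorded under
the strict/inclusive conventions.

## Numerical choices and scale

Window means use cumulative sums with missing-base counts, so a single
pass serves both the means and the disqualification rule. The
at-threshold JS case is solved by `uniroot` to 1e-14 and nudged 1e-9 to
the specific side so file round-trips cannot flip it. Expression values
are generated at fixed decimal precision so written bundles are
byte-stable. Problem sizes — a 300-kb genome, ~40 candidate transcripts,
100 random 50-kb annotations for the oracle-equivalence suite — keep the
full test suite around five minutes on one core while still exercising
every code path; all statistics are linear or near-linear in genome size,
so real chromosomes scale without algorithmic changes.

## Known limitations

- Classification consumes one transcript model per candidate; isoform
  collapsing is upstream.
- The lncNAT/sense decision order is fixed (documented above) rather than
  reporting multi-label conflicts.
- The conservation track is held per-base in memory; whole-genome tracks
  for large genomes would want an indexed store (bigWig is deliberately
  out of scope, bedGraph only).
- Statistical tests comparing classes (t, Wilcoxon, Kolmogorov–Smirnov)
  are left to the caller, who gets the per-transcript vectors.
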