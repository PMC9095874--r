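---
title: "Methods: quantifying circular RNA isoforms with circlet"
author: "circlet maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: quantifying circular RNA isoforms with circlet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlet)
suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
  library(S4Vectors)
})
```

# The problem

Circular RNAs arise from back-splicing: a downstream 5' splice site (the
donor) is joined to an upstream 3' splice site (the acceptor), producing a
covalently closed molecule with no cap or poly-A tail. A read that crosses
the resulting back-splice junction (BSJ) cannot come from a linear
transcript, so BSJ-crossing reads are the unambiguous currency of circular
abundance. For a multi-isoform locus such as a long non-coding RNA with
dozens of annotated transcripts, the first obstacle is purely
book-keeping: different transcripts contain different exon subsets, so exon
numbering is isoform-dependent. `circlet` works throughout in a collapsed
**meta-isoform** coordinate frame — the interval union of all annotated
exons of the gene, renumbered 1..n in transcriptional order — and builds on
that frame a pipeline covering BSJ calling and filtering, circular and
linear abundance quantification, sequence-feature analyses of back-spliced
splice sites and flanking introns, miRNA seed-site density comparison, and
donor-level association of circular/linear expression ratios with
proliferation phenotypes and SNP genotypes.

# The meta-isoform frame

`buildMetaIsoform()` merges exons with `GenomicRanges::reduce()`. Exons
that merely abut (the end of one immediately followed by the start of the
next) are merged by default — annotation unions read "overlapping"
inclusively, and distinct abutting exons at a locus almost always reflect
alternative boundary annotation of one underlying exon — but
`strictOverlap = TRUE` restricts merging to genuine overlaps. Numbering is
transcriptional: for a minus-strand gene, exon 1 is the genomically
rightmost merged interval, and intron names (`"4_5"`) always refer to the
transcriptional flanking exons.

Internally all intervals are `GRanges` (1-based, closed), because interval
arithmetic is delegated to `IRanges`; the BED and GTF readers and writers
convert at the I/O boundary, so on-disk conventions (0-based half-open BED,
1-based closed GTF) are preserved exactly.

Splice sites are attributed to meta-exons by `attributeSpliceSite()` with a
default tolerance of 2 nt. Junction callers wobble by a base or two around
true boundaries; 2 nt absorbs that without ever bridging the gap between
two distinct exon boundaries at realistic exon spacing. Sites farther than
the tolerance from every boundary of the requested kind get an intragenic
label, `"between_<up>_<down>"`, rendered in transcriptional order — cryptic
intronic splice sites participate in back-splicing and must stay visible
rather than being forced onto the nearest exon.

# BSJ calling, filtering and abundance

`detectBsj()` consumes *segmented* read alignments (a plain-text stand-in
for a chimeric aligner's output): a read crossing a BSJ aligns in two
segments whose genomic order is inverted relative to read order. Only
two-segment reads are considered — reads with more segments are counted
and skipped, since multi-chimeric reads need upstream resolution this
package deliberately does not attempt — and the junction key is
`(chrom, start, end, strand)`, the BED-style circRNA identity that makes
set comparisons with clone-derived junctions well defined.

The **high-confidence filter** removes junctions seen in a single
individual with a single supporting read. Both published wordings of this
rule are provided: `mode = "or"` (at least two individuals *or* at least
two reads; the default) and `mode = "and"` (both). Note the two agree on
singleton junctions and differ only on single-individual multi-read
junctions; with per-library noise junctions of one read each, either mode
removes exactly the noise.

Circular abundance is **JPM**, junctions per million mapped reads:
`reads * 1e6 / mapped`. Each BSJ read testifies to one circular molecule,
so JPM is a molecule-count rate; the conservation identity
`sum(JPM * mapped / 1e6) = total BSJ reads` holds exactly and is enforced
in the tests. Linear expression enters as TPM (computed upstream; this
package never re-estimates it), and the per-gene circular/linear ratio is
summed JPM over TPM with an `Inf` sentinel (never a silent drop) when a
gene has junction reads but no measurable linear expression. The
"expressed gene" threshold is TPM > 5, the same cutoff the motif analyses
use, and is configurable.

qPCR expression uses the `-(Ct_target - mean(Ct_refs))` convention, so
higher values mean more template and one template doubling adds one log2
unit. RNase R retention, compartment (cytoplasmic/nuclear) ratios, group
tests (Welch t and exact-where-possible Mann-Whitney), pairwise-complete
correlation matrices, and an iterative Fisher-exact enrichment loop (test
all terms, BH-adjust, accept the best term below threshold, remove its
genes from query and background, repeat — so reported terms never owe
their significance to shared genes) complete the quantification layer.
Missing-data policy: pairwise-complete observations for correlations,
listwise deletion for regressions; constant features yield `NA` with a
warning, never a silent zero.

# Sequence features of back-spliced sites

**Splice-site strength.** Windows are the conventional 9 nt around the 5'
splice site (exon-relative -3:+6) and 23 nt around the 3' splice site
(-20:+3). The default model is a position weight matrix with pseudocount 1
trained on user-supplied site sets, scored as log2 odds against a uniform
background; externally computed maximum-entropy score tables are consumed
directly when available (`maxEntModel()`), since those tables are an
external artefact the pipeline should use but not re-derive. Group
comparisons use a **bootstrap test**: each score group is resampled with
replacement and the p-value is the fraction of resamples in which the
group means violate the stated alternative. Groups (not pooled labels) are
resampled; the p-value uses the add-one convention `(s + 1)/(reps + 1)` so
it always lies in (0, 1], and two identical constant groups give exactly
1. Default 10,000 replicates, seed mandatory for reproducibility.

**Inverted complementarity.** `findComplementaryRegions()` searches one
intron against the reverse complement of a partner intron under
blastn-style scoring (match +2, mismatch -3, gap open 5, gap extend 2 as
positive costs, first gapped base open + extend). The engine is an
affine-gap (Gotoh) local alignment in C++, iterated greedily: the best
local alignment is traced back, its positions in both sequences are
masked, and the search repeats, so reported hits never overlap and come
out in descending score order. A hit must score strictly above 25 and
contain an exact match run of at least the word size (7 nt) — the seed
requirement of a word-based aligner. The documented limitation is the
flip side: a high-scoring alignment with no 7-mer exact core is discarded;
on random sequence such alignments above the threshold are rare, and the
test suite verifies agreement with an independent full Smith-Waterman
oracle on all pairs up to 300 nt whenever an exact core exists. A
random-pairing null (`randomPairingNull()`) draws non-occurring intron
pairings uniformly without replacement, seeded.

**Repeats and motifs.** Repeat-overlap enrichment marks each region by any
overlap of at least 1 bp and compares classes with a two-sided Fisher
exact test. Motif occurrence takes IUPAC strings (ambiguity codes
honoured), reports the percentage of regions in each class containing at
least one match (sense strand by default — these are transcribed regions),
and tests enrichment one-sided. Introns are split into splice-site
proximal and distal halves, the proximal half abutting the named site and
taking the extra base at odd lengths. De novo motif discovery is out of
scope; discovered motifs are supplied as strings.

# miRNA seed-site density

Exons are classified **circular** when present in at least 10% of
Sanger-sequenced clones, otherwise **linear**; class membership follows
this clone rule alone, with no dual-membership weighting. miRNAs are kept
when their mean expression across the supplied datasets exceeds 5 RPM
(strictly — a mean of exactly 5 is excluded). Target sites are seed
matches: the exon sense strand is scanned for the reverse complement of
miRNA positions 2-8 (7mer-m8 by default; 6mer, 7mer-A1 and 8mer are
selectable), with overlapping matches counted at distinct start positions.
This is a deliberate desk-scale stand-in for hybridisation-energy
predictors: no thermodynamic duplex scoring, conservation filtering or 3'
supplementary pairing. Densities are sites per kb of each class's total
exon length — stable numbers at single-gene exon scales — and the summary
counts how many miRNAs are denser in each class.

# Phenotype and genotype association

The proliferation index is the percentage of BrdU+/insulin+ beta cells in
15 mmol/L glucose over the same percentage in 5 mmol/L.
`quartileAssociation()` bins donors into ratio quartiles and tests
monotonicity by Spearman correlation plus a Q1-vs-Q4 rank test. Binning is
rank-based with stable order for ties: the partition property (bin sizes
differing by at most one) is guaranteed, which a value-based cut with ties
to the lower bin cannot promise under heavy ties; with continuous ratios
the two coincide. `genotypeAssociation()` fits ordinary least squares of
the trait on 0/1/2 risk-allele dosage per SNP (risk-allele coding keeps
the sign of beta aligned with risk), listwise-deletes missing genotypes
per SNP, flags monomorphic SNPs untestable, and Benjamini-Hochberg adjusts
across the tested SNPs. A trait with zero variance is answered with
beta 0, p 1 rather than a 0/0 t statistic. Diabetic donors are included by
default — isoform abundances did not differ detectably by diabetes status
in the motivating data — and can be excluded by subsetting the donor
table.

# The synthetic data generator

Every input the pipeline consumes can be generated with planted ground
truth, so each stage is testable offline against a known answer. The
defaults are the study conditions, fixed up front:

* **Gene**: 22 exons (280-520 nt), introns 350-650 nt with the introns
  upstream of exons 2 and 4 and downstream of exon 16 lengthened 2.2-fold
  (back-spliced exons tend to be flanked by long introns). Transcript
  models are emitted whose exon union reproduces the meta-isoform exactly.
* **Circles**: 17 planted BSJs whose splice sites involve 11 distinct
  exons (acceptors concentrated on exons 2, 4 and 5; donors on 7, 10 and
  16) plus 3 intragenic positions; weights are skewed so the 7-5 pairing
  alone carries 22% of BSJ reads and exon 5 acts as acceptor in just over
  half of them.
* **Sequencing**: 5 individuals, each as an untreated and an RNase R
  library of 8,000 junction-spanning molecules; 30.8% of molecules are
  circular and linear molecules survive digestion with probability 0.1,
  so the library-normalised BSJ enrichment expectation is
  `1 / (0.308 + 0.692 * 0.1) = 2.65` while raw linear-junction counts
  deplete about tenfold. Mapped totals are 100x the junction reads.
  Five cryptic singleton junctions (one read, one library) are planted as
  noise for the high-confidence filter to remove.
* **Clones**: 115 Sanger clones over 35 distinct junctions; the 10
  best-supported clone junctions coincide with the 10 most-used planted
  BSJs, giving a 10/17 = 58.8% validation fraction, and clone exon spans
  yield a circular exon class (exons 2-16) about twice the total length
  of the linear-only class.
* **Inverted repeats**: a 20-nt exact repeat between the introns flanking
  the exon-2 acceptor and the exon-7 donor (alignment score exactly
  20 x 2 = 40) and a 30-nt repeat with one internal mismatch between the
  exon-2 and exon-16 flanking introns (29 x 2 - 3 = 55), so the stronger
  pairing is 16-2. Planted regions are insulated by deliberately
  mismatching flank guards, which pins the expected alignment scores
  exactly regardless of the random flanking sequence.
* **miRNA panel**: 70 miRNAs — 43 planted with higher seed-site density
  in circular exons (the top one at a 4.38-fold density ratio), 18 with
  higher density in linear exons, 9 below the 5 RPM expression cutoff.
  Exon sequences use a reduced {A, C} background and seed-target words of
  the form `G` + six letters from {A, C, T}: a match must place its
  single `G` at a planted word start, so planted site counts are exact by
  construction and recovery tests are deterministic.
* **Cohort**: 122 donors; genotypes binomial(2, MAF); log2 expression from
  a one-latent-factor model giving circular-circular Pearson correlations
  near 0.87 and circular-linear near 0.65; the rs564398 dosage adds 0.5
  log2 units per risk allele to every circular assay (and hence to the
  circ/lin ratio) while three co-SNPs are null; proliferation index
  (first 45 donors) = 2.2 - 0.25 x log2(circ/lin) + N(0, 0.3), floored at
  0.05; stimulation index independent of the ratio; 10 diabetic donors.
* **Genome-wide table**: 1,000 genes with independent log-normal TPM
  (sd 1.2) and JPM (sd 1.6); since log(JPM/TPM) inherits -log(TPM), the
  expected Spearman correlation of TPM with the ratio is
  `-1.2 / sqrt(1.2^2 + 1.6^2) = -0.6`. One planted high-abundance
  circRNA host, `synCIRBP` (a synthetic stand-in, not the real CIRBP
  locus), sits at the 97th JPM percentile and exercises the ranking
  computation.

One master seed drives independent per-stage sub-seeds, so any stage can
be regenerated in isolation and the same seed gives byte-identical output.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* the analysis relies
on: inverted read-segment order at BSJs, compositional RNase R enrichment,
correlated circular assays, planted sequence elements with exact expected
scores, and additive genotype effects. It does not model sequencing error,
quality scores, alignment ambiguity, GC or length biases, cell-type
mixture, or hybridisation thermodynamics; exon sequences are
reduced-alphabet by design. Passing recovery tests therefore demonstrates
that the implementations compute the intended quantities correctly, not
that the pipeline is robust to artefacts real aligners and libraries
introduce. One consequence of kb-scale random introns is worth noting:
chance complementary regions above the score threshold can and do occur
between long intron pairs; these are genuine alignments (the independent
Smith-Waterman oracle confirms them), not search artefacts, so recovery
tests assert exact planted-hit recovery plus oracle agreement rather than
the absence of any additional hit.

# Numerical choices and degenerate inputs

* Tolerances: splice-site attribution 2 nt; clone-junction matching 2 nt
  per boundary; complementarity threshold strictly above 25 with word
  size 7.
* Sentinels: `Inf` for ratios with zero denominators but positive
  numerators (flagged, retained); `NaN` for 0/0 densities; `NA` (with
  warning) for zero 5 mmol/L denominators and for correlations of
  constant features.
* Tie-breaks: greedy non-overlapping hit selection by descending score;
  enrichment-loop ties by adjusted p, then raw p, then term name;
  quartile ties by stable rank order; odd intron splits give the proximal
  half the extra base.
* Pseudocounts: 1 per PWM cell; 0.5 per exon count in coverage folds.
* Calibration checks (null uniformity, nominal type-I rates) are asserted
  within binomial sampling bands rather than as hard thresholds, because
  the empirical rate of a correctly calibrated test exceeds its nominal
  level about half the time at finite replication.

Problem sizes in the shipped tests and acceptance script — 8,000 junction
molecules per library, 500 association replicates, 200 calibration
replicates, alignment oracles on pairs up to 300 nt — were chosen as the
smallest sizes at which the sampling error of each checked quantity is
comfortably inside its assertion band.

# Known limitations

* The complementarity search is seed-limited (documented above) and
  reports raw scores only; no E-value statistics.
* Seed matching is presence-based; miRNA target confirmation requires
  orthogonal evidence.
* GT-AG validation of called junctions is not performed by default: the
  caller consumes pre-segmented alignments whose aligner already imposed
  splice models.
* TPM estimation and the RNase R statistical correction of external
  quantifiers are consumed, not re-implemented; `readCiriquantTable()`
  accepts an adjusted-count column when one is supplied.
* The cohort model is additive on the log2 ratio with homoscedastic
  noise; age interactions and insulin-secretion modelling beyond the
  shared quartile/association machinery are out of scope.

# A worked run

```{r pipeline, eval = FALSE}
spec <- syntheticSpec(seed = 1)
gene <- generateGene(spec)
reads <- simulateReads(gene)
bsj <- detectBsj(reads$segments, gene$meta,
                 mappedReads = setNames(reads$libraries$mapped_reads,
                                        reads$libraries$library))
hc <- filterHighConfidence(bsj)
nrow(hc)                         # 17 junctions
treatmentEnrichment(bsj)         # ~2.65
validateAgainstClones(hc, gene$clones)$validatedFraction   # 0.588
```

The README shows the full worked example with the numbers it prints;
`scripts/acceptance.R` recomputes all headline quantities from scratch.
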