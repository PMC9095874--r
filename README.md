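# circlet

Back-splice junction detection and circular RNA isoform analysis for
multi-isoform loci.

Circular RNAs (circRNAs) are produced by back-splicing: a downstream 5'
splice site (donor) joins an upstream 3' splice site (acceptor), yielding a
covalently closed molecule that resists exonucleolytic digestion. Because a
read crossing the back-splice junction (BSJ) cannot derive from a linear
transcript, BSJ-crossing reads measure circular abundance directly.
`circlet` is for researchers characterising the circular isoform repertoire
of a complex locus — typically a long non-coding RNA with many annotated
transcripts — from RNase R / mock-treated RNA-seq together with qPCR
cohorts, Sanger-validated clone junctions, and donor genotype/phenotype
tables.

## What it computes

* **Meta-isoform frame** — all annotated exons of a gene collapsed into the
  interval union, renumbered 1..n in transcriptional order
  (`buildMetaIsoform()`); every downstream result is expressed in these
  exon numbers, with splice sites attributed to exon boundaries within a
  configurable tolerance (`attributeSpliceSite()`).
* **BSJ calling and filtering** — junctions from segmented chimeric read
  alignments (`detectBsj()`), a high-confidence filter removing
  single-individual single-read junctions (`filterHighConfidence()`),
  splice-site pairing frequencies, RNase R enrichment folds, and validation
  against clone-derived junction sets.
* **Abundance** — circular expression as junctions per million mapped
  reads, JPM = reads x 10^6 / mapped; per-gene circular/linear ratios
  JPM/TPM; qPCR log2 expression (-dCt), RNase R retention, compartment
  ratios, correlation matrices, group tests, and an iterative Fisher-exact
  enrichment that never reports overlapping gene sets.
* **Sequence features** — PWM or maxEnt-table splice-site scoring over the
  conventional 9-nt donor (-3:+6) and 23-nt acceptor (-20:+3) windows with
  a bootstrap group test; a seed-and-extend affine-gap search (match +2,
  mismatch -3, gap open 5, gap extend 2; hits > 25 with a 7-nt exact core)
  for inverted complementary regions between flanking introns;
  repeat-overlap and IUPAC motif occurrence tests.
* **miRNA seed sites** — exon classification by the 10% clone rule, a
  strict > 5 mean-RPM expression filter, seed-complement counting
  (7mer-m8 and friends), and per-kb site-density comparison between
  circular and linear exon classes.
* **Phenotype/genotype** — proliferation index (% BrdU+ insulin+ cells at
  15 over 5 mmol/L glucose), quartile association of circ/lin ratios with
  phenotypes, and additive-dosage OLS association with
  Benjamini-Hochberg correction across SNPs.
* **Synthetic data** — a generator (`syntheticSpec()`, `generateGene()`,
  `simulateReads()`, `simulateCohort()`, ...) that produces every input the
  pipeline consumes with planted ground truth, used as the oracle for all
  recovery tests.

## Worked example

```r
library(circlet)

spec  <- syntheticSpec(seed = 1)     # the default study conditions
gene  <- generateGene(spec)          # annotation, sequences, ground truth
reads <- simulateReads(gene)         # segmented alignments, 5 donors x 2 treatments

bsj <- detectBsj(reads$segments, gene$meta,
                 mappedReads = setNames(reads$libraries$mapped_reads,
                                        reads$libraries$library))
hc <- filterHighConfidence(bsj)
hc
#> class: BsjExperiment
#> dim: 17 10
#> ...
#> total BSJ reads: 7380
```

Seventeen junctions survive the high-confidence filter (the five planted
singleton noise junctions are removed). Their pairing frequencies, named
`<donor exon>-<acceptor exon>`:

```r
head(spliceSiteUsage(hc)$pairs, 5)
#>   pair donor_label acceptor_label reads proportion
#> 1  7-5           7              5  1616 0.21897019
#> 2 10-5          10              5   898 0.12168022
#> 3 16-5          16              5   806 0.10921409
#> 4 16-4          16              4   689 0.09336043
#> 5 16-2          16              2   375 0.05081301
```

The 7-5 isoform alone contributes ~22% of BSJ reads and exon 5 acts as
acceptor in just over half of them. RNase R digestion enriches BSJ
abundance as designed (circular fraction 0.308, linear retention 0.1 give
an expected compositional fold of 2.65):

```r
treatmentEnrichment(bsj)
#> [1] 2.637512
validateAgainstClones(hc, gene$clones)$validatedFraction
#> [1] 0.5882353        # 10 of 17 junctions confirmed by Sanger clones
```

On the 122-donor cohort, the planted rs564398 dosage effect on the log2
circular/linear ratio is recovered while the three co-located SNPs stay
null:

```r
cohort <- simulateCohort(spec)
genotypeAssociation(cohort,
                    c("rs564398", "rs2383208", "rs10757283", "rs10811661"),
                    "log2_circ_lin_ratio")
#>          snp   n       beta        se        raw_p   adjusted_p testable
#> 1   rs564398 122  0.4808929 0.1065319 1.495357e-05 5.981427e-05     TRUE
#> 2  rs2383208 122 -0.1434669 0.1167677 2.216064e-01 3.842387e-01     TRUE
#> 3 rs10757283 122 -0.0242194 0.1040696 8.163729e-01 8.163729e-01     TRUE
#> 4 rs10811661 122 -0.1309990 0.1227899 2.881790e-01 3.842387e-01     TRUE
```

The estimated beta of 0.48 log2 units per risk allele sits within one
standard error of the planted 0.5, and higher ratios accompany lower
proliferation indices (`quartileAssociation()`).

See `vignettes/circlet-methods.Rmd` for the models, parameter choices and
generator design.

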