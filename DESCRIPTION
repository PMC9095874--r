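Package: circlet
Title: Back-Splice Junction Detection and Circular RNA Isoform Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterising circular RNA isoforms of multi-exon
    genes from RNase R / mock-treated RNA-seq experiments. Collapses
    transcript annotations into a meta-isoform coordinate frame, calls
    back-splice junctions (BSJs) from segmented chimeric read alignments,
    applies a high-confidence support filter, and quantifies circular
    abundance as junctions per million mapped reads (JPM) alongside linear
    TPMs. Includes sequence-feature analyses of back-spliced splice sites
    (PWM or maxEnt-table scoring with bootstrap group tests), a
    seed-and-extend affine-gap search for inverted complementary regions in
    flanking introns, repeat-overlap and motif occurrence tests, miRNA
    seed-site density comparisons between circular and linear exon classes,
    and donor-level association of circular/linear expression ratios with
    proliferation phenotypes and SNP genotypes. A synthetic-data module
    generates every input the pipeline consumes, with planted ground truth
    used as the oracle in recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
biocViews: Transcriptomics, Sequencing, GeneExpression, Annotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
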