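#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#'   reduce gaps countOverlaps findOverlaps granges sort
#' @importFrom IRanges IRanges ranges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
#'   assays assayNames
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   vcountPattern consensusMatrix writeXStringSet subseq
#' @importFrom stats cor cor.test fisher.test lm median p.adjust quantile
#'   rbinom rnorm runif rlnorm t.test wilcox.test setNames complete.cases coef
#' @importFrom utils write.table read.delim head
#' @useDynLib circlet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MetaIsoform: a gene's collapsed, renumbered exon model
#'
#' A `MetaIsoform` holds the interval union of all annotated exons of a gene,
#' merged where overlapping (optionally also where abutting) and renumbered
#' 1..n in transcriptional order: exon 1 is the 5'-most meta-exon on the gene
#' strand, so for minus-strand genes it is the genomically rightmost merged
#' interval. It is the coordinate frame for splice-site attribution, BSJ
#' naming, intron pairing and exon classification.
#'
#' @slot geneId single gene identifier.
#' @slot exons [GenomicRanges::GRanges] of merged meta-exons, all on one
#'   chromosome and strand, genomically sorted, with an integer metadata
#'   column `exon_number` giving the transcriptional-order numbering.
#'
#' @seealso [buildMetaIsoform()], [metaExons()], [metaIntrons()],
#'   [attributeSpliceSite()]
#' @export
setClass("MetaIsoform",
  slots = c(geneId = "character", exons = "GRanges"))

setValidity("MetaIsoform", function(object) {
  ex <- object@exons
  msg <- character()
  if (length(object@geneId) != 1L || is.na(object@geneId))
    msg <- c(msg, "geneId must be a single non-NA string")
  if (length(ex) == 0L)
    msg <- c(msg, "meta-isoform must contain at least one exon")
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    msg <- c(msg, "meta-exons must lie on a single chromosome")
  str <- unique(as.character(strand(ex)))
  if (length(str) != 1L || !str %in% c("+", "-"))
    msg <- c(msg, "meta-exons must share a single strand ('+' or '-')")
  if (!"exon_number" %in% names(mcols(ex)))
    msg <- c(msg, "meta-exons need an 'exon_number' metadata column")
  else {
    n <- length(ex)
    num <- mcols(ex)$exon_number
    expected <- if (identical(str, "-")) rev(seq_len(n)) else seq_len(n)
    if (is.unsorted(start(ex)))
      msg <- c(msg, "meta-exons must be sorted by genomic start")
    else if (!identical(as.integer(num), as.integer(expected)))
      msg <- c(msg, "exon_number must be consecutive 1..n in transcriptional order")
    if (n > 1L && any(start(ex)[-1L] <= end(ex)[-n]))
      msg <- c(msg, "meta-exons must be pairwise disjoint and non-abutting-merged")
  }
  if (length(msg)) msg else TRUE
})

#' BsjExperiment: back-splice junctions with per-library read support
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. Rows are
#' back-splice junctions (BSJs): the range runs from the genomically leftmost
#' to the rightmost back-spliced boundary, and the BSJ identity key is
#' (chrom, start, end, strand). Row metadata carries the splice-site
#' attribution of the acceptor (the BSJ "3' exon") and donor (the "5' exon"):
#' `acceptor_pos`, `acceptor_label`, `acceptor_offset`, and the `donor_*`
#' triple, plus a human-readable `pair` label `"<donor>-<acceptor>"` following
#' the donor-acceptor naming convention for circular isoforms (e.g. "7-5").
#' Columns are sequencing libraries; `colData` must provide `sample_id` (the
#' individual — several libraries, e.g. RNase R and mock, may share one),
#' `treatment` (`"rnase_r"` or `"untreated"`), and `mapped_reads` (library
#' size). The `"counts"` assay holds BSJ-crossing read counts; an optional
#' `"adjusted"` assay holds externally corrected counts.
#'
#' @seealso [detectBsj()], [filterHighConfidence()], [spliceSiteUsage()],
#'   [nIndividuals()], [readCiriquantTable()]
#' @export
setClass("BsjExperiment", contains = "RangedSummarizedExperiment")

setValidity("BsjExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else if (any(assay(object, "counts") < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  need <- c("sample_id", "treatment", "mapped_reads")
  miss <- setdiff(need, names(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (length(object) && any(start(rowRanges(object)) >= end(rowRanges(object))))
    msg <- c(msg, "junction start must be < end")
  if (length(msg)) msg else TRUE
})

#' @describeIn MetaIsoform construct directly from a gene id and a merged,
#'   numbered exon `GRanges` (most users should use [buildMetaIsoform()]).
#' @param geneId gene identifier.
#' @param exons numbered meta-exon `GRanges` (see slot description).
#' @export
MetaIsoform <- function(geneId, exons) {
  new("MetaIsoform", geneId = as.character(geneId), exons = exons)
}

#' Construct a BsjExperiment
#'
#' @param junctions `GRanges` of BSJs with the attribution metadata columns
#'   described in [BsjExperiment-class].
#' @param counts junction x library matrix of BSJ read counts.
#' @param colData `DataFrame`/data.frame with `sample_id`, `treatment`,
#'   `mapped_reads` per library.
#' @param adjusted optional matrix of externally adjusted counts.
#' @return a [BsjExperiment-class] object.
#' @export
BsjExperiment <- function(junctions, counts, colData, adjusted = NULL) {
  counts <- as.matrix(counts)
  assays <- list(counts = counts)
  if (!is.null(adjusted)) assays$adjusted <- as.matrix(adjusted)
  se <- SummarizedExperiment(assays = assays, rowRanges = junctions,
                             colData = DataFrame(colData))
  new("BsjExperiment", se)
}

setMethod("show", "MetaIsoform", function(object) {
  ex <- object@exons
  cat("MetaIsoform for gene", object@geneId, "\n")
  cat(" ", length(ex), "meta-exons on", as.character(seqnames(ex))[1L],
      paste0("(", as.character(strand(ex))[1L], ")"),
      "spanning", min(start(ex)), "-", max(end(ex)), "\n")
  cat("  total exonic length:", sum(width(ex)), "nt;",
      if (length(ex) > 1L) length(ex) - 1L else 0L, "introns\n")
})

setMethod("show", "BsjExperiment", function(object) {
  callNextMethod()
  if (length(object)) {
    cat("total BSJ reads:", sum(assay(object, "counts")), "\n")
  }
})
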