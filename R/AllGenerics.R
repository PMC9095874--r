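#' Accessors for MetaIsoform and BsjExperiment objects
#'
#' `geneId()` returns the gene identifier; `metaExons()` the numbered
#' meta-exon `GRanges`; `metaIntrons()` the derived intron `GRanges`, named
#' `"<upstream>_<downstream>"` by the transcriptional exon numbers they
#' separate (so intron `"4_5"` lies between meta-exons 4 and 5 on the gene
#' strand); `geneStrand()` the gene strand.
#'
#' For [BsjExperiment-class] objects, `nIndividuals()` returns, per junction,
#' the number of distinct individuals (`colData$sample_id`) with support of at
#' least one read, and `totalSupport()` the per-junction read total across all
#' libraries.
#'
#' @param x a `MetaIsoform` or `BsjExperiment`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("metaExons", function(x) standardGeneric("metaExons"))

#' @rdname accessors
#' @export
setGeneric("metaIntrons", function(x) standardGeneric("metaIntrons"))

#' @rdname accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("totalSupport", function(x) standardGeneric("totalSupport"))

#' @rdname accessors
setMethod("geneId", "MetaIsoform", function(x) x@geneId)

#' @rdname accessors
setMethod("metaExons", "MetaIsoform", function(x) x@exons)

#' @rdname accessors
setMethod("geneStrand", "MetaIsoform",
  function(x) as.character(strand(x@exons))[1L])

#' @rdname accessors
setMethod("metaIntrons", "MetaIsoform", function(x) {
  ex <- x@exons
  n <- length(ex)
  if (n < 2L) {
    gr <- GRanges()
    return(gr)
  }
  introns <- GRanges(seqnames(ex)[-1L],
                     IRanges(end(ex)[-n] + 1L, start(ex)[-1L] - 1L),
                     strand = strand(ex)[-1L])
  # transcript numbering of the flanking exons
  up <- mcols(ex)$exon_number[-n]
  dn <- mcols(ex)$exon_number[-1L]
  if (geneStrand(x) == "-") { tmp <- up; up <- dn; dn <- tmp }
  names(introns) <- paste0(pmin(up, dn), "_", pmax(up, dn))
  mcols(introns)$upstream_exon <- pmin(up, dn)
  mcols(introns)$downstream_exon <- pmax(up, dn)
  introns
})

#' @rdname accessors
setMethod("nIndividuals", "BsjExperiment", function(x) {
  counts <- assay(x, "counts")
  ind <- as.character(colData(x)$sample_id)
  if (ncol(counts) == 0L) return(integer(nrow(counts)))
  bySample <- t(rowsum(t(counts > 0) * 1L, group = ind))
  as.integer(rowSums(bySample > 0))
})

#' @rdname accessors
setMethod("totalSupport", "BsjExperiment", function(x) {
  rowSums(assay(x, "counts"))
})
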