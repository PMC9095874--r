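#' Collapse transcript models into a meta-isoform
#'
#' Merges the exons of all annotated transcripts of a gene into a single
#' non-redundant exon model and renumbers the merged exons 1..n in
#' transcriptional order (for minus-strand genes exon 1 is the genomically
#' rightmost merged interval). Overlapping exons always merge; abutting exons
#' (the 3' end of one immediately followed by the 5' start of the next) merge
#' by default, since annotation unions read "overlapping" inclusively, but
#' `strictOverlap = TRUE` keeps them separate.
#'
#' @param transcripts either a [GenomicRanges::GRangesList] with one element
#'   per transcript (exon ranges; all elements on one chromosome and strand),
#'   or a data.frame with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based closed coordinates) and optionally `gene_id`.
#' @param geneId gene identifier for the result; taken from a `gene_id`
#'   column/metadata when omitted.
#' @param strictOverlap if `TRUE`, only strictly overlapping exons merge.
#' @return a [MetaIsoform-class].
#' @examples
#' tx <- data.frame(transcript_id = c("t1", "t1", "t2", "t2"),
#'                  chrom = "chr9", strand = "+",
#'                  start = c(101, 301, 151, 301), end = c(200, 400, 250, 400))
#' buildMetaIsoform(tx, geneId = "g")   # meta-exons [101,250], [301,400]
#' @export
buildMetaIsoform <- function(transcripts, geneId = NULL, strictOverlap = FALSE) {
  if (is.data.frame(transcripts)) {
    if (nrow(transcripts) == 0L) stop("no exons supplied")
    if (is.null(geneId) && "gene_id" %in% names(transcripts))
      geneId <- unique(transcripts$gene_id)
    gr <- GRanges(transcripts$chrom,
                  IRanges(transcripts$start, transcripts$end),
                  strand = transcripts$strand)
    exons <- gr
  } else if (is(transcripts, "GRangesList")) {
    if (length(transcripts) == 0L || sum(lengths(transcripts)) == 0L)
      stop("no exons supplied")
    if (any(lengths(transcripts) == 0L))
      stop("transcript with empty exon list")
    exons <- unlist(transcripts, use.names = FALSE)
    if (is.null(geneId) && "gene_id" %in% names(mcols(exons)))
      geneId <- unique(mcols(exons)$gene_id)
  } else if (is(transcripts, "GRanges")) {
    if (length(transcripts) == 0L) stop("no exons supplied")
    exons <- transcripts
    if (is.null(geneId) && "gene_id" %in% names(mcols(exons)))
      geneId <- unique(mcols(exons)$gene_id)
  } else {
    stop("transcripts must be a GRangesList, GRanges or data.frame")
  }
  if (is.null(geneId)) stop("geneId is required when no gene_id is annotated")
  if (length(geneId) != 1L)
    stop("transcripts span multiple gene_ids: ", paste(geneId, collapse = ", "))
  if (length(unique(as.character(seqnames(exons)))) > 1L)
    stop("transcripts of one gene must share a chromosome")
  str <- unique(as.character(strand(exons)))
  if (length(str) != 1L || !str %in% c("+", "-"))
    stop("transcripts of one gene must share a '+' or '-' strand")
  merged <- reduce(granges(exons),
                   min.gapwidth = if (strictOverlap) 0L else 1L)
  merged <- GenomicRanges::sort(merged)
  n <- length(merged)
  mcols(merged)$exon_number <-
    if (str == "-") rev(seq_len(n)) else seq_len(n)
  MetaIsoform(geneId, merged)
}

#' Attribute genomic splice-site positions to meta-exons
#'
#' A donor (5' splice site) belongs to the exon whose transcript-3' boundary
#' it matches; an acceptor (3' splice site) to the exon whose transcript-5'
#' boundary it matches. On the plus strand the donor boundary is the exon's
#' last genomic base and the acceptor boundary its first; on the minus strand
#' the roles swap. A site within `tolerance` nt of the relevant boundary is
#' attributed to that exon with a signed offset (positive = transcriptionally
#' downstream of the boundary). Otherwise the site gets an intragenic label
#' `"between_<up>_<down>"` naming the flanking exon numbers in
#' transcriptional order (or `"within_<exon>"` for a position in an exon
#' interior), with the offset measured from the nearest boundary of the
#' requested kind.
#'
#' @param meta a [MetaIsoform-class].
#' @param position integer vector of 1-based genomic positions (the boundary
#'   base of the junction).
#' @param kind `"donor"` or `"acceptor"` (recycled along `position`).
#' @param tolerance maximum nt of boundary wobble still attributed to an
#'   annotated exon (default 2, a common junction-caller jitter).
#' @param flank positions farther than this outside the gene span are an
#'   error (default 1000).
#' @return data.frame with columns `position`, `kind`, `label`, `exon`
#'   (integer, NA for intragenic), `offset`.
#' @export
attributeSpliceSite <- function(meta, position, kind = c("donor", "acceptor"),
                                tolerance = 2L, flank = 1000L) {
  stopifnot(is(meta, "MetaIsoform"))
  kind <- match.arg(kind, several.ok = TRUE)
  kind <- rep_len(kind, length(position))
  ex <- metaExons(meta)
  str <- geneStrand(meta)
  num <- mcols(ex)$exon_number
  lo <- min(start(ex)); hi <- max(end(ex))
  if (any(position < lo - flank | position > hi + flank))
    stop("splice-site position outside the gene span +/- flank")
  donorBoundary <- if (str == "+") end(ex) else start(ex)
  acceptorBoundary <- if (str == "+") start(ex) else end(ex)
  sgn <- if (str == "+") 1L else -1L

  res <- lapply(seq_along(position), function(i) {
    p <- position[i]
    b <- if (kind[i] == "donor") donorBoundary else acceptorBoundary
    d <- sgn * (p - b)                      # transcript-direction offset
    j <- which.min(abs(d))
    if (abs(d[j]) <= tolerance)
      return(list(label = as.character(num[j]), exon = num[j],
                  offset = as.integer(d[j])))
    # intragenic: locate between which transcript exons the position falls
    hitExon <- which(p >= start(ex) & p <= end(ex))
    if (length(hitExon)) {
      lab <- paste0("within_", num[hitExon[1L]])
    } else {
      genLeft <- findInterval(p, end(ex))   # exons fully left of p (genomic)
      if (genLeft == 0L || genLeft == length(ex)) {
        lab <- if (genLeft == 0L) "upstream_flank" else "downstream_flank"
        if (str == "-") lab <- if (genLeft == 0L) "downstream_flank" else "upstream_flank"
      } else {
        e1 <- num[genLeft]; e2 <- num[genLeft + 1L]
        lab <- paste0("between_", min(e1, e2), "_", max(e1, e2))
      }
    }
    list(label = lab, exon = NA_integer_, offset = as.integer(d[j]))
  })
  data.frame(position = as.integer(position), kind = kind,
             label = vapply(res, `[[`, "", "label"),
             exon = vapply(res, `[[`, NA_integer_, "exon"),
             offset = vapply(res, `[[`, NA_integer_, "offset"))
}

#' Read transcript exon models from GTF/GFF or BED12
#'
#' GTF/GFF `exon` features are grouped by `transcript_id`; BED12 blocks are
#' expanded to exons, one transcript per record. Coordinate conventions of
#' each format (1-based closed GTF, 0-based half-open BED) are handled by the
#' importer, so the returned ranges are ordinary 1-based `GRanges`.
#'
#' @param file path to a `.gtf`/`.gff`/`.gff3` or `.bed` (BED12) file.
#' @param format override the format guessed from the extension.
#' @return a [GenomicRanges::GRangesList], one element per transcript, with
#'   `gene_id` metadata on the exons when the source provides it.
#' @export
readTranscripts <- function(file, format = c("auto", "gtf", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed12"
              else if (grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3"
              else "gtf"
  }
  if (format == "bed12") {
    bed <- rtracklayer::import(file, format = "BED")
    grl <- rtracklayer::blocks(bed)
    if (is.null(names(grl)) || any(names(grl) == ""))
      names(grl) <- paste0("tx", seq_along(grl))
    return(grl)
  }
  gr <- rtracklayer::import(file, format = format)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", file)
  keep <- intersect(c("gene_id", "transcript_id"), names(mcols(gr)))
  mcols(gr) <- mcols(gr)[, keep, drop = FALSE]
  GenomicRanges::split(gr, mcols(gr)$transcript_id)
}

#' Export a meta-isoform
#'
#' `writeMetaIsoformBed()` writes a single BED12 record whose blocks are the
#' meta-exons. `metaExonTable()` returns (and optionally writes as TSV) the
#' per-exon table with BED-convention 0-based half-open coordinates.
#'
#' @param meta a [MetaIsoform-class].
#' @param file output path; for `metaExonTable()`, `NULL` skips writing.
#' @return `metaExonTable()` returns the exon data.frame invisibly-written or
#'   not; `writeMetaIsoformBed()` returns `file` invisibly.
#' @export
writeMetaIsoformBed <- function(meta, file) {
  ex <- metaExons(meta)
  span <- range(ex)
  rel <- IRanges::shift(ranges(ex), 1L - start(span))
  rec <- span
  mcols(rec)$name <- geneId(meta)
  mcols(rec)$score <- 0L
  mcols(rec)$blocks <- IRanges::IRangesList(rel)
  rtracklayer::export(rec, file, format = "BED")
  invisible(file)
}

#' @rdname writeMetaIsoformBed
#' @export
metaExonTable <- function(meta, file = NULL) {
  ex <- metaExons(meta)
  tab <- data.frame(exon_number = mcols(ex)$exon_number,
                    chrom = as.character(seqnames(ex)),
                    start = start(ex) - 1L,   # BED convention on disk
                    end = end(ex),
                    strand = as.character(strand(ex)))
  tab <- tab[order(tab$exon_number), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(file))
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
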