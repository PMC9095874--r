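#' Call back-splice junctions from segmented read alignments
#'
#' A back-splice junction (BSJ) joins a downstream 5' splice site (donor) to
#' an upstream 3' splice site (acceptor); a read crossing it aligns in two
#' segments whose genomic order is inverted relative to their order in the
#' read. `detectBsj()` considers reads with exactly two segments on the
#' gene's chromosome: when the transcriptionally downstream segment comes
#' first in read order, one BSJ is emitted spanning from the acceptor-side
#' boundary to the donor-side boundary; co-linear reads yield nothing. Reads
#' with more than two segments are skipped with a logged count, and malformed
#' segments (`end < start`) drop their read with a warning.
#'
#' @param segments data.frame of aligned read segments with columns
#'   `read_id`, `sample_id`, `treatment` (`"rnase_r"`/`"untreated"`),
#'   `chrom`, `start`, `end` (1-based closed), `strand`, `segment`
#'   (order of the segment within the read).
#' @param meta [MetaIsoform-class] providing the coordinate frame; splice
#'   sites are attributed with [attributeSpliceSite()].
#' @param tolerance boundary wobble passed to [attributeSpliceSite()].
#' @param mappedReads named numeric vector of per-library mapped-read totals
#'   (names `"<sample_id>.<treatment>"`), or a single number recycled; `NA`
#'   when unknown.
#' @return a [BsjExperiment-class] with one column per library present in
#'   `segments` (even libraries contributing no BSJ).
#' @export
detectBsj <- function(segments, meta, tolerance = 2L, mappedReads = NA_real_) {
  stopifnot(is(meta, "MetaIsoform"))
  need <- c("read_id", "sample_id", "treatment", "chrom", "start", "end",
            "strand", "segment")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments lacks column(s): ", paste(miss, collapse = ", "))
  chrom <- as.character(seqnames(metaExons(meta)))[1L]
  gstr <- geneStrand(meta)

  lib <- paste(segments$sample_id, segments$treatment, sep = ".")
  libs <- unique(data.frame(library = lib, sample_id = segments$sample_id,
                            treatment = segments$treatment,
                            stringsAsFactors = FALSE))
  libs <- libs[order(libs$library), , drop = FALSE]

  bad <- segments$end < segments$start
  if (any(bad)) {
    badReads <- unique(segments$read_id[bad])
    warning(length(badReads), " read(s) with malformed segments (end < start) skipped")
    segments <- segments[!segments$read_id %in% badReads, , drop = FALSE]
    lib <- paste(segments$sample_id, segments$treatment, sep = ".")
  }

  nseg <- table(segments$read_id)
  multi <- sum(nseg > 2L)
  if (multi > 0L)
    message(multi, " read(s) with >2 segments skipped (BSJ calling uses two-segment reads)")
  keepReads <- names(nseg)[nseg == 2L]
  seg2 <- segments[segments$read_id %in% keepReads, , drop = FALSE]

  emptyResult <- function() {
    cd <- DataFrame(sample_id = libs$sample_id, treatment = libs$treatment,
                    mapped_reads = rep_len(unname(mappedReads), nrow(libs)),
                    row.names = libs$library)
    BsjExperiment(GRanges(), matrix(0, 0L, nrow(libs),
                                    dimnames = list(NULL, libs$library)), cd)
  }
  if (nrow(seg2) == 0L) return(emptyResult())

  seg2 <- seg2[order(seg2$read_id, seg2$segment), , drop = FALSE]
  first <- seg2[seq(1L, nrow(seg2), by = 2L), , drop = FALSE]
  second <- seg2[seq(2L, nrow(seg2), by = 2L), , drop = FALSE]

  onChrom <- first$chrom == chrom & second$chrom == chrom &
    first$strand == gstr & second$strand == gstr
  first <- first[onChrom, , drop = FALSE]
  second <- second[onChrom, , drop = FALSE]
  if (nrow(first) == 0L) return(emptyResult())

  # first-in-read segment transcriptionally downstream of the second
  isBsj <- if (gstr == "+") first$start > second$start
           else first$start < second$start
  first <- first[isBsj, , drop = FALSE]
  second <- second[isBsj, , drop = FALSE]
  if (nrow(first) == 0L) return(emptyResult())

  if (gstr == "+") {
    jstart <- second$start            # acceptor-side boundary (leftmost)
    jend <- first$end                 # donor-side boundary (rightmost)
    accPos <- jstart; donPos <- jend
  } else {
    jstart <- first$start             # donor boundary (leftmost)
    jend <- second$end                # acceptor boundary (rightmost)
    accPos <- jend; donPos <- jstart
  }
  key <- paste(chrom, jstart, jend, gstr, sep = ":")
  libOf <- paste(first$sample_id, first$treatment, sep = ".")
  counts <- table(factor(key, levels = sort(unique(key))),
                  factor(libOf, levels = libs$library))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))

  u <- !duplicated(key)
  ord <- match(rownames(counts), key[u])
  ustart <- jstart[u][ord]; uend <- jend[u][ord]
  uacc <- accPos[u][ord]; udon <- donPos[u][ord]

  acc <- attributeSpliceSite(meta, uacc, "acceptor", tolerance = tolerance)
  don <- attributeSpliceSite(meta, udon, "donor", tolerance = tolerance)
  jx <- GRanges(chrom, IRanges(ustart, uend), strand = gstr)
  mcols(jx)$acceptor_pos <- uacc
  mcols(jx)$acceptor_label <- acc$label
  mcols(jx)$acceptor_offset <- acc$offset
  mcols(jx)$donor_pos <- udon
  mcols(jx)$donor_label <- don$label
  mcols(jx)$donor_offset <- don$offset
  mcols(jx)$pair <- paste0(don$label, "-", acc$label)
  names(jx) <- rownames(counts)

  cd <- DataFrame(sample_id = libs$sample_id, treatment = libs$treatment,
                  mapped_reads = rep_len(unname(mappedReads), nrow(libs)),
                  row.names = libs$library)
  if (!is.null(names(mappedReads)))
    cd$mapped_reads <- unname(mappedReads[rownames(cd)])
  BsjExperiment(jx, counts, cd)
}

#' High-confidence BSJ filter
#'
#' Keeps junctions supported beyond the singleton level: under `mode = "or"`
#' (default) a junction passes when it is seen in at least two individuals
#' *or* carries at least two reads in total; `mode = "and"` requires both.
#' The two modes reflect the two readings of "present in more than one
#' individual and/or supported by more than one junction read"; a junction
#' seen once in one individual is removed under either.
#'
#' @param x a [BsjExperiment-class].
#' @param mode `"or"` or `"and"`.
#' @return the filtered [BsjExperiment-class] (always a row subset of `x`).
#' @export
filterHighConfidence <- function(x, mode = c("or", "and")) {
  mode <- match.arg(mode)
  nInd <- nIndividuals(x)
  tot <- totalSupport(x)
  keep <- if (mode == "or") nInd >= 2L | tot >= 2L else nInd >= 2L & tot >= 2L
  x[keep, ]
}

#' Splice-site pairing frequencies of back-splice junctions
#'
#' Summarises how BSJ reads distribute over donor-acceptor pairings and over
#' individual splice sites: per-pair read proportions (reads of the pair over
#' total BSJ reads) and the marginal proportion of reads in which each
#' attributed site acts as acceptor or as donor.
#'
#' @param x a [BsjExperiment-class] with at least one junction.
#' @return list with `pairs` (data.frame: `pair`, `donor_label`,
#'   `acceptor_label`, `reads`, `proportion`), `acceptorMarginal` and
#'   `donorMarginal` (named proportion vectors, each summing to 1).
#' @export
spliceSiteUsage <- function(x) {
  if (nrow(x) == 0L) stop("no junctions")
  reads <- totalSupport(x)
  total <- sum(reads)
  if (total == 0) stop("zero total BSJ reads")
  rr <- rowRanges(x)
  pairs <- data.frame(pair = mcols(rr)$pair,
                      donor_label = mcols(rr)$donor_label,
                      acceptor_label = mcols(rr)$acceptor_label,
                      reads = unname(reads))
  pairs <- stats::aggregate(reads ~ pair + donor_label + acceptor_label,
                            data = pairs, FUN = sum)
  pairs$proportion <- pairs$reads / total
  pairs <- pairs[order(-pairs$reads), , drop = FALSE]
  rownames(pairs) <- NULL
  accM <- tapply(pairs$reads, pairs$acceptor_label, sum) / total
  donM <- tapply(pairs$reads, pairs$donor_label, sum) / total
  list(pairs = pairs,
       acceptorMarginal = accM[order(-accM)],
       donorMarginal = donM[order(-donM)])
}

#' RNase R enrichment of back-splice junction reads
#'
#' Library-size-normalised fold change of BSJ read abundance in RNase R
#' treated versus untreated libraries, over junctions falling in `region`
#' (default: all junctions). Counts are scaled to counts-per-million mapped
#' reads before summing within each treatment group.
#'
#' @param x a [BsjExperiment-class] with both treatments in `colData` and
#'   known `mapped_reads`.
#' @param region optional `GRanges` restricting the junctions considered.
#' @return the treated/untreated fold change (`Inf` with a warning when the
#'   untreated sum is zero).
#' @export
treatmentEnrichment <- function(x, region = NULL) {
  if (!all(c("rnase_r", "untreated") %in% colData(x)$treatment))
    stop("both 'rnase_r' and 'untreated' libraries are required")
  if (any(is.na(colData(x)$mapped_reads)))
    stop("mapped_reads must be known for all libraries")
  if (!is.null(region))
    x <- IRanges::subsetByOverlaps(x, region)
  counts <- assay(x, "counts")
  cpm <- sweep(counts, 2L, colData(x)$mapped_reads / 1e6, "/")
  treated <- sum(cpm[, colData(x)$treatment == "rnase_r", drop = FALSE])
  untreated <- sum(cpm[, colData(x)$treatment == "untreated", drop = FALSE])
  if (untreated == 0) {
    warning("zero untreated BSJ reads in region; returning Inf")
    return(Inf)
  }
  treated / untreated
}

#' Cross-validate RNA-seq BSJs against clone-derived junctions
#'
#' Matches RNA-seq junctions to junctions observed in Sanger-sequenced
#' divergent-PCR clones by their (acceptor, donor) genomic boundary pair,
#' allowing `tolerance` nt of wobble on each boundary.
#'
#' @param x a [BsjExperiment-class].
#' @param clones data.frame with columns `acceptor_pos` and `donor_pos`
#'   (1-based genomic boundary positions of distinct clone junctions).
#' @param tolerance per-boundary matching tolerance in nt.
#' @return list: `validatedFraction` (fraction of RNA-seq junctions matched
#'   by a clone), `reverseFraction` (fraction of clone junctions matched by
#'   RNA-seq), `validated` (logical per RNA-seq junction), `nClones`.
#' @export
validateAgainstClones <- function(x, clones, tolerance = 2L) {
  if (nrow(x) == 0L || nrow(clones) == 0L) stop("both junction sets must be non-empty")
  rr <- rowRanges(x)
  a <- mcols(rr)$acceptor_pos; d <- mcols(rr)$donor_pos
  matchOne <- function(ai, di, as, ds)
    any(abs(as - ai) <= tolerance & abs(ds - di) <= tolerance)
  validated <- mapply(matchOne, a, d,
                      MoreArgs = list(as = clones$acceptor_pos, ds = clones$donor_pos))
  reverse <- mapply(matchOne, clones$acceptor_pos, clones$donor_pos,
                    MoreArgs = list(as = a, ds = d))
  list(validatedFraction = mean(validated),
       reverseFraction = mean(reverse),
       validated = validated,
       nClones = nrow(clones))
}

#' Per-exon coverage fold change between treatments
#'
#' Treated/untreated ratio of pseudocount-guarded counts-per-million, per
#' exon. Exons retained in circles gain coverage under RNase R while purely
#' linear exons are depleted.
#'
#' @param treated,untreated per-exon read counts (equal length).
#' @param libTreated,libUntreated mapped-read totals of the two groups.
#' @param pseudocount added to each count before scaling (default 0.5).
#' @return numeric vector of per-exon fold changes.
#' @export
exonCoverageFold <- function(treated, untreated, libTreated, libUntreated,
                             pseudocount = 0.5) {
  stopifnot(length(treated) == length(untreated),
            libTreated > 0, libUntreated > 0)
  ((treated + pseudocount) / libTreated) /
    ((untreated + pseudocount) / libUntreated)
}

#' Count read segments overlapping each meta-exon
#'
#' @param segments segment data.frame as for [detectBsj()].
#' @param meta a [MetaIsoform-class].
#' @return matrix exons x libraries of overlapping segment counts, rows in
#'   transcriptional exon order.
#' @export
countExonCoverage <- function(segments, meta) {
  ex <- metaExons(meta)
  lib <- paste(segments$sample_id, segments$treatment, sep = ".")
  libs <- sort(unique(lib))
  gr <- GRanges(segments$chrom, IRanges(segments$start, segments$end))
  out <- sapply(libs, function(l)
    countOverlaps(ex, gr[lib == l], ignore.strand = TRUE))
  out <- matrix(out, nrow = length(ex), dimnames = list(NULL, libs))
  ord <- order(mcols(ex)$exon_number)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- mcols(ex)$exon_number[ord]
  out
}

#' BSJ table I/O
#'
#' `writeBsjBed()` writes a BED6+ table (0-based half-open coordinates,
#' `name` = `<donor>-<acceptor>` pair label, `score` = total reads) followed
#' by one count column per library. `readCiriquantTable()` reads a
#' CIRIquant-style long TSV with columns `chrom`, `start`, `end`, `strand`,
#' `sample_id`, `treatment`, `count`, and optionally `adjusted_count` and
#' `mapped_reads`, and assembles a [BsjExperiment-class] against a
#' meta-isoform.
#'
#' @param x a [BsjExperiment-class].
#' @param file output / input path.
#' @param meta a [MetaIsoform-class] used for splice-site attribution.
#' @param tolerance attribution tolerance in nt.
#' @export
writeBsjBed <- function(x, file) {
  rr <- rowRanges(x)
  counts <- assay(x, "counts")
  tab <- data.frame(chrom = as.character(seqnames(rr)),
                    start = start(rr) - 1L,
                    end = end(rr),
                    name = mcols(rr)$pair,
                    score = unname(rowSums(counts)),
                    strand = as.character(strand(rr)))
  tab <- cbind(tab, as.data.frame(counts))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeBsjBed
#' @export
readCiriquantTable <- function(file, meta, tolerance = 2L) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "sample_id", "treatment", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(tab$chrom, tab$start, tab$end, tab$strand, sep = ":")
  lib <- paste(tab$sample_id, tab$treatment, sep = ".")
  ukey <- sort(unique(key)); ulib <- sort(unique(lib))
  counts <- matrix(0, length(ukey), length(ulib), dimnames = list(ukey, ulib))
  counts[cbind(match(key, ukey), match(lib, ulib))] <- tab$count
  adjusted <- NULL
  if ("adjusted_count" %in% names(tab)) {
    adjusted <- matrix(0, length(ukey), length(ulib), dimnames = list(ukey, ulib))
    adjusted[cbind(match(key, ukey), match(lib, ulib))] <- tab$adjusted_count
  }
  u <- !duplicated(key)
  ord <- match(ukey, key[u])
  uchrom <- tab$chrom[u][ord]; ustart <- tab$start[u][ord]
  uend <- tab$end[u][ord]; ustr <- tab$strand[u][ord]
  accPos <- ifelse(ustr == "+", ustart, uend)
  donPos <- ifelse(ustr == "+", uend, ustart)
  acc <- attributeSpliceSite(meta, accPos, "acceptor", tolerance = tolerance)
  don <- attributeSpliceSite(meta, donPos, "donor", tolerance = tolerance)
  jx <- GRanges(uchrom, IRanges(ustart, uend), strand = ustr)
  mcols(jx)$acceptor_pos <- accPos
  mcols(jx)$acceptor_label <- acc$label
  mcols(jx)$acceptor_offset <- acc$offset
  mcols(jx)$donor_pos <- donPos
  mcols(jx)$donor_label <- don$label
  mcols(jx)$donor_offset <- don$offset
  mcols(jx)$pair <- paste0(don$label, "-", acc$label)
  names(jx) <- ukey
  mapped <- rep(NA_real_, length(ulib))
  if ("mapped_reads" %in% names(tab)) {
    mp <- tapply(tab$mapped_reads, lib, function(v) v[1L])
    mapped <- unname(mp[ulib])
  }
  sid <- tapply(tab$sample_id, lib, function(v) v[1L])[ulib]
  trt <- tapply(tab$treatment, lib, function(v) v[1L])[ulib]
  cd <- DataFrame(sample_id = unname(sid), treatment = unname(trt),
                  mapped_reads = mapped, row.names = ulib)
  BsjExperiment(jx, counts, cd, adjusted = adjusted)
}
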