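#' Extract splice-site windows from a meta-isoform
#'
#' Returns the fixed-width sequence windows used for splice-site strength
#' scoring: 9 nt around each 5' splice site (donor; exon-relative -3:+6) and
#' 23 nt around each 3' splice site (acceptor; -20:+3). Windows are reported
#' 5'->3' on the gene strand.
#'
#' @param meta a [MetaIsoform-class].
#' @param genome a [Biostrings::DNAStringSet] (or `DNAString`) holding the
#'   chromosome sequence the meta-isoform lives on.
#' @return list of two named character vectors, `donor` (9-mers) and
#'   `acceptor` (23-mers), named by exon number; windows that would run off
#'   the sequence are dropped.
#' @export
spliceSiteWindows <- function(meta, genome) {
  ex <- metaExons(meta)
  chrom <- as.character(seqnames(ex))[1L]
  seq <- if (is(genome, "DNAStringSet")) genome[[chrom]] else genome
  str <- geneStrand(meta)
  num <- mcols(ex)$exon_number
  getw <- function(from, to) {
    ok <- from >= 1L & to <= length(seq)
    out <- rep(NA_character_, length(from))
    if (any(ok)) {
      v <- as.character(Biostrings::extractAt(seq, IRanges(from[ok], to[ok])))
      if (str == "-")
        v <- as.character(reverseComplement(DNAStringSet(v)))
      out[ok] <- v
    }
    out
  }
  if (str == "+") {
    donor <- getw(end(ex) - 2L, end(ex) + 6L)
    acceptor <- getw(start(ex) - 20L, start(ex) + 2L)
  } else {
    donor <- getw(start(ex) - 6L, start(ex) + 2L)
    acceptor <- getw(end(ex) - 2L, end(ex) + 20L)
  }
  names(donor) <- names(acceptor) <- num
  ord <- order(num)
  list(donor = donor[ord][!is.na(donor[ord])],
       acceptor = acceptor[ord][!is.na(acceptor[ord])])
}

#' Splice-site strength models
#'
#' `trainSpliceSitePwm()` builds a position weight matrix with pseudocounts
#' from a set of equal-length site windows; `maxEntModel()` wraps an
#' externally supplied maximum-entropy score table (one score per enumerated
#' k-mer, as distributed with maxEntScan-style tools). `scoreSpliceSite()`
#' scores a window under either model: PWM scores are log2 odds against a
#' uniform background (so an uninformative all-0.25 column contributes 0 and
#' a window of `N`s scores 0); table models are direct lookups.
#'
#' @param sites character vector or `DNAStringSet` of equal-length training
#'   windows (alphabet ACGT; `N` tolerated and ignored in counting).
#' @param pseudocount added to each base count per column (default 1).
#' @param scores named numeric vector: k-mer -> score.
#' @param window a single site window (character), length matching the model.
#' @param model a model from `trainSpliceSitePwm()` or `maxEntModel()`.
#' @return `scoreSpliceSite()` returns a single numeric score (higher =
#'   stronger site).
#' @examples
#' pwm <- trainSpliceSitePwm(c("CAGGTAAGT", "AAGGTGAGT", "CAGGTAAGA"))
#' scoreSpliceSite("CAGGTAAGT", pwm)
#' @export
trainSpliceSitePwm <- function(sites, pseudocount = 1) {
  sites <- as.character(sites)
  if (length(sites) == 0L) stop("no training sites")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("training windows must share one width")
  counts <- consensusMatrix(DNAStringSet(sites))[c("A", "C", "G", "T"), ,
                                                 drop = FALSE]
  counts <- counts + pseudocount
  prob <- sweep(counts, 2L, colSums(counts), "/")
  structure(list(type = "pwm", prob = prob, width = w), class = "spliceSiteModel")
}

#' @rdname trainSpliceSitePwm
#' @export
maxEntModel <- function(scores) {
  if (is.null(names(scores)) || length(scores) == 0L)
    stop("scores must be a named (k-mer) vector")
  w <- unique(nchar(names(scores)))
  if (length(w) != 1L) stop("all k-mers must share one width")
  structure(list(type = "table", scores = scores, width = w),
            class = "spliceSiteModel")
}

#' @rdname trainSpliceSitePwm
#' @export
scoreSpliceSite <- function(window, model) {
  stopifnot(inherits(model, "spliceSiteModel"), length(window) == 1L)
  window <- toupper(as.character(window))
  if (nchar(window) != model$width)
    stop("window length ", nchar(window), " does not match model width ",
         model$width)
  chars <- strsplit(window, "")[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("window contains characters outside ACGTN")
  if (model$type == "table") {
    if (any(chars == "N")) stop("table models cannot score N-containing windows")
    s <- model$scores[window]
    if (is.na(s)) stop("k-mer absent from score table: ", window)
    return(unname(s))
  }
  idx <- match(chars, c("A", "C", "G", "T"))
  sum(vapply(seq_along(chars), function(i) {
    if (is.na(idx[i])) 0 else log2(model$prob[idx[i], i] / 0.25)
  }, numeric(1L)))
}

#' Bootstrap comparison of splice-site score groups
#'
#' Resamples each score group with replacement `reps` times and reports the
#' proportion of resamples in which the group means violate the alternative:
#' for `alternative = "A_less"`, p is the fraction of resamples with
#' `mean(A*) >= mean(B*)` (with the add-one convention `(s + 1) / (reps + 1)`
#' so p always lies in (0, 1]; two identical constant groups give exactly 1).
#'
#' @param groupA,groupB numeric score vectors (each >= 2 values).
#' @param reps bootstrap replicates (default 10000; < 100 warns).
#' @param seed RNG seed for reproducibility (set when not `NULL`).
#' @param alternative `"A_less"` (is A's mean smaller?) or `"A_greater"`.
#' @return bootstrap p-value in (0, 1].
#' @export
bootstrapScoreTest <- function(groupA, groupB, reps = 10000, seed = NULL,
                               alternative = c("A_less", "A_greater")) {
  alternative <- match.arg(alternative)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 scores")
  if (reps < 100) warning("fewer than 100 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  nA <- length(groupA); nB <- length(groupB)
  mA <- colMeans(matrix(sample(groupA, nA * reps, replace = TRUE), nrow = nA))
  mB <- colMeans(matrix(sample(groupB, nB * reps, replace = TRUE), nrow = nB))
  s <- if (alternative == "A_less") sum(mA >= mB) else sum(mA <= mB)
  (s + 1) / (reps + 1)
}

#' Intron lengths grouped by back-splicing role
#'
#' For each meta-exon, reports the lengths of its transcriptionally upstream
#' and downstream introns together with the exon's back-splicing role
#' (`"3p"` = provides the back-spliced acceptor, `"5p"` = provides the
#' donor, `"none"`). Terminal exons lack one intron (NA).
#'
#' @param meta a [MetaIsoform-class] with at least 2 exons.
#' @param bsjRoles named character vector exon_number -> role; exons not
#'   named default to `"none"`.
#' @return data.frame: `exon`, `role`, `upstream_length`, `downstream_length`.
#' @export
intronLengthTable <- function(meta, bsjRoles = NULL) {
  ex <- metaExons(meta)
  if (length(ex) < 2L) stop("meta-isoform needs at least 2 exons")
  introns <- metaIntrons(meta)
  n <- length(ex)
  num <- sort(mcols(ex)$exon_number)
  up <- setNames(rep(NA_integer_, n), num)
  dn <- up
  iu <- mcols(introns)$upstream_exon     # intron lies downstream of this exon
  idn <- mcols(introns)$downstream_exon
  dn[as.character(iu)] <- width(introns)
  up[as.character(idn)] <- width(introns)
  role <- rep("none", n)
  names(role) <- num
  if (!is.null(bsjRoles)) {
    shared <- intersect(names(bsjRoles), names(role))
    role[shared] <- bsjRoles[shared]
  }
  data.frame(exon = as.integer(num), role = unname(role),
             upstream_length = unname(up), downstream_length = unname(dn))
}

#' Find inverted complementary regions between two introns
#'
#' Searches `seqA` against the reverse complement of `seqB` for high-scoring
#' local alignments under blastn-style scoring (match +2, mismatch -3, gap
#' open 5, gap extend 2 as positive costs; the first gapped base costs
#' open + extend). Hits are extracted greedily by descending score with
#' aligned positions masked so reported hits never overlap, must score
#' strictly above `minScore`, and must contain an exact match run of at
#' least `wordSize` bases (the seed requirement of a word-based aligner;
#' alignments lacking such a core are discarded, a documented limitation).
#' Hit coordinates in B are mapped back to the original (un-complemented)
#' intron coordinates.
#'
#' @param seqA,seqB intron sequences (character or `DNAString`), ACGT.
#' @param reward,penalty match/mismatch scores (+2 / -3).
#' @param gapOpen,gapExtend positive gap costs (5 / 2).
#' @param wordSize minimum exact-match core (7).
#' @param minScore strict score threshold (25).
#' @return data.frame with one row per hit: `startA`, `endA`, `startB`,
#'   `endB` (1-based, in the original sequences), `score`, `length`
#'   (alignment columns), `maxRun`.
#' @examples
#' r <- paste(sample(c("A","C","G","T"), 20, TRUE), collapse = "")
#' # a 20-nt exact inverted repeat scores 20 * 2 = 40
#' @export
findComplementaryRegions <- function(seqA, seqB, reward = 2, penalty = -3,
                                     gapOpen = 5, gapExtend = 2,
                                     wordSize = 7, minScore = 25) {
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  empty <- data.frame(startA = integer(), endA = integer(),
                      startB = integer(), endB = integer(),
                      score = numeric(), length = integer(),
                      maxRun = integer())
  if (nchar(a) < wordSize || nchar(b) < wordSize) {
    warning("sequence shorter than wordSize; no hits")
    return(empty)
  }
  brc <- as.character(reverseComplement(DNAString(b)))
  hits <- .sw_local_hits(a, brc, reward, penalty, gapOpen, gapExtend, minScore)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$maxRun >= wordSize, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  nB <- nchar(b)
  startB <- nB - hits$endB + 1L
  endB <- nB - hits$startB + 1L
  out <- data.frame(startA = hits$startA, endA = hits$endA,
                    startB = startB, endB = endB,
                    score = hits$score, length = hits$length,
                    maxRun = hits$maxRun)
  out[order(-out$score), , drop = FALSE]
}

#' Sample non-occurring intron pairings as a null set
#'
#' Draws `n` pairings uniformly without replacement from the universe of
#' candidate pairings minus those observed in BSJs, reproducibly under
#' `seed`.
#'
#' @param observedPairs,universePairs two-column data.frames/matrices of
#'   pairing identifiers (order within a pair is meaningful).
#' @param n number of null pairings to draw.
#' @param seed RNG seed (set when not `NULL`).
#' @return data.frame of `n` sampled pairings with the input column names.
#' @export
randomPairingNull <- function(observedPairs, universePairs, n, seed = NULL) {
  obs <- as.data.frame(observedPairs); uni <- as.data.frame(universePairs)
  if (ncol(obs) != 2L || ncol(uni) != 2L) stop("pairings must have 2 columns")
  keyO <- paste(obs[[1L]], obs[[2L]], sep = "\r")
  keyU <- paste(uni[[1L]], uni[[2L]], sep = "\r")
  avail <- which(!keyU %in% keyO & !duplicated(keyU))
  if (length(avail) == 0L) stop("no non-occurring pairings available")
  if (n > length(avail))
    stop("requested ", n, " pairings but only ", length(avail), " available")
  if (!is.null(seed)) set.seed(seed)
  take <- sort(sample(avail, n))
  out <- uni[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repeat-overlap enrichment between region classes
#'
#' Marks each region as repeat-overlapping (any overlap of >= 1 bp with the
#' repeat annotation) and compares target vs other regions with a two-sided
#' Fisher exact test on the 2x2 presence table.
#'
#' @param targetRegions,otherRegions `GRanges` of the two region classes
#'   (e.g. introns flanking back-spliced exons vs the rest).
#' @param repeats `GRanges` of repeat annotations on the same coordinates.
#' @return list: `table` (2x2 matrix), `p`, `oddsRatio`,
#'   `targetOverlap`/`otherOverlap` logical vectors.
#' @export
repeatOverlapEnrichment <- function(targetRegions, otherRegions, repeats) {
  ot <- countOverlaps(targetRegions, repeats, ignore.strand = TRUE) > 0
  oo <- countOverlaps(otherRegions, repeats, ignore.strand = TRUE) > 0
  tab <- matrix(c(sum(ot), sum(!ot), sum(oo), sum(!oo)), nrow = 2L,
                dimnames = list(c("overlap", "no_overlap"),
                                c("target", "other")))
  ft <- fisher.test(tab)
  list(table = tab, p = ft$p.value, oddsRatio = unname(ft$estimate),
       targetOverlap = ot, otherOverlap = oo)
}

#' Split an intron into splice-site-proximal and distal halves
#'
#' Partitions an intron into two equal regions relative to the named splice
#' site; with an odd length the proximal half receives the extra base. The
#' proximal half abuts the named site: the intron's 3' splice site
#' (acceptor) sits at its transcript-downstream end, the 5' splice site
#' (donor) at its transcript-upstream end.
#'
#' @param intron a single-range `GRanges` (strand-aware) or `IRanges`
#'   (treated as plus strand) of width >= 2.
#' @param siteKind `"acceptor_3ss"` or `"donor_5ss"`.
#' @return list of two ranges, `proximal` and `distal`, of the same class as
#'   the input; `proximal` and `distal` partition the intron.
#' @export
splitIntronRegions <- function(intron, siteKind = c("acceptor_3ss", "donor_5ss")) {
  siteKind <- match.arg(siteKind)
  isGR <- is(intron, "GRanges")
  if (length(intron) != 1L) stop("one intron at a time")
  w <- width(intron)
  if (w < 2L) stop("intron length must be >= 2")
  str <- if (isGR) as.character(strand(intron)) else "+"
  s <- start(intron); e <- end(intron)
  wProx <- as.integer(ceiling(w / 2))
  # genomic side the named splice site sits on
  siteAtRight <- (siteKind == "acceptor_3ss") == (str != "-")
  if (siteAtRight) {
    prox <- c(e - wProx + 1L, e); dist <- c(s, e - wProx)
  } else {
    prox <- c(s, s + wProx - 1L); dist <- c(s + wProx, e)
  }
  mk <- function(lim) {
    if (isGR) GRanges(seqnames(intron), IRanges(lim[1L], lim[2L]), strand = str)
    else IRanges(lim[1L], lim[2L])
  }
  list(proximal = mk(prox), distal = mk(dist))
}

#' Motif occurrence rates in two region classes
#'
#' Percent of foreground and background regions containing at least one
#' match to a motif (IUPAC string, ambiguity codes honoured), with a
#' one-sided Fisher exact test for foreground enrichment on the
#' presence/absence 2x2 table.
#'
#' @param motif IUPAC motif string (e.g. `"TGACGTCA"`, `"RY"`).
#' @param fgRegions,bgRegions `DNAStringSet` (or character vectors) of
#'   region sequences.
#' @param bothStrands also search the reverse complement (default FALSE:
#'   sense only, the orientation of a transcribed region).
#' @return list: `percentFg`, `percentBg`, `fisherP`, `table`.
#' @export
motifOccurrence <- function(motif, fgRegions, bgRegions, bothStrands = FALSE) {
  fg <- DNAStringSet(fgRegions); bg <- DNAStringSet(bgRegions)
  if (grepl("^N+$", toupper(motif)))
    warning("degenerate motif matches every position")
  hasHit <- function(x) {
    h <- vcountPattern(motif, x, fixed = FALSE) > 0
    if (bothStrands)
      h <- h | vcountPattern(as.character(reverseComplement(DNAString(motif))),
                             x, fixed = FALSE) > 0
    h
  }
  hf <- hasHit(fg); hb <- hasHit(bg)
  tab <- matrix(c(sum(hf), sum(!hf), sum(hb), sum(!hb)), nrow = 2L,
                dimnames = list(c("match", "no_match"), c("fg", "bg")))
  ft <- fisher.test(tab, alternative = "greater")
  list(percentFg = 100 * mean(hf), percentBg = 100 * mean(hb),
       fisherP = ft$p.value, table = tab)
}
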