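#' Study-condition specification for the synthetic data generator
#'
#' Bundles every tunable of the synthetic cohort into one object. The
#' defaults describe the study conditions the pipeline is designed for: a
#' 22-exon gene with 17 planted back-splice junctions whose splice sites
#' involve 11 distinct exons plus 3 intragenic positions (exon 5 acting as
#' acceptor in just over half of BSJ reads), five individuals sequenced as
#' RNase R / mock pairs, a circular molecule fraction and linear retention
#' chosen so RNase R enriches BSJ reads about 2.65-fold, 115 Sanger clones
#' over 35 distinct junctions of which 10 coincide with planted BSJs
#' (10/17 = 58.8% validation), two inverted repeats planted in the introns
#' flanking the exon-2 acceptor and the exon-7/exon-16 donors (expected
#' alignment scores 40 and 55), a 70-miRNA panel with 43 circular-biased and
#' 18 linear-biased site plants (top density fold 4.38) plus 9
#' under-expressed miRNAs, a 122-donor qPCR cohort with an additive
#' rs564398-dosage effect on the log2 circular/linear ratio and a negative
#' ratio-proliferation slope, and a 1000-gene genome-wide abundance table
#' whose log-scale spreads give a Spearman correlation of about -0.6 between
#' linear TPM and the circular/linear ratio.
#'
#' @param seed master RNG seed; each generator stage derives an independent
#'   sub-seed from it so stages can be regenerated in isolation.
#' @param nExons,exonLengthRange,intronLengthRange gene geometry (nt).
#' @param longIntrons introns (by `"<up>_<down>"` name) lengthened by
#'   `longIntronFactor`, emulating the long introns flanking back-spliced
#'   exons.
#' @param circles data.frame of planted circles: `acceptor`/`donor` meta-exon
#'   numbers (NA for intragenic sites, located mid-intron via
#'   `acceptorIntron`/`donorIntron` = upstream exon of the host intron) and
#'   relative `weight` (must sum to 1).
#' @param circFraction fraction of junction-spanning molecules that are
#'   circular before treatment.
#' @param pRetainLinear survival probability of a linear molecule under
#'   RNase R (circles always survive).
#' @param bsjCrossFraction fraction of circular junction reads that cross
#'   the back-splice junction (the rest are internal, co-linear).
#' @param nSamples,readsPerSample,mappedPerJunctionRead sequencing design;
#'   each sample yields an `untreated` and an `rnase_r` library of
#'   `readsPerSample` junction reads, with `mapped_reads` set to
#'   `readsPerSample * mappedPerJunctionRead`.
#' @param segmentLength aligned segment length of simulated reads.
#' @param noiseJunctions number of cryptic singleton BSJs (one read in one
#'   library; removed by the high-confidence filter).
#' @param nClones total Sanger clones.
#' @param mirnaCircBiased,mirnaLinBiased,mirnaUnexpressed panel composition.
#' @param topMirnaFold target circular/linear density fold of the
#'   top-planted miRNA.
#' @param nDonors,mafs,betaGenotype,assayNoiseSd cohort genotype-expression
#'   design (beta on the log2 circ/lin ratio per risk-allele copy).
#' @param circCircR,circLinR target correlations among circular assays and
#'   between circular and linear assays.
#' @param prolifIntercept,prolifSlope,prolifNoiseSd,nProliferationDonors
#'   proliferation index = intercept - slope * log2(circ/lin) + noise,
#'   measured in a donor subset.
#' @param nStimulationDonors donors with a (ratio-independent) stimulation
#'   index.
#' @param nDiabetic diabetic donors (flagged, included by default
#'   downstream).
#' @param nGenesGenomeWide,muLogTpm,sdLogTpm,muLogJpm,sdLogJpm genome-wide
#'   abundance table design (natural-log scales).
#' @return a list of class `"circletSpec"`.
#' @export
syntheticSpec <- function(seed = 1L,
                          nExons = 22L,
                          exonLengthRange = c(280L, 520L),
                          intronLengthRange = c(350L, 650L),
                          longIntrons = c("1_2", "3_4", "16_17"),
                          longIntronFactor = 2.2,
                          circles = defaultCircles(),
                          circFraction = 0.308,
                          pRetainLinear = 0.1,
                          bsjCrossFraction = 0.3,
                          nSamples = 5L,
                          readsPerSample = 8000L,
                          mappedPerJunctionRead = 100L,
                          segmentLength = 60L,
                          noiseJunctions = 5L,
                          nClones = 115L,
                          mirnaCircBiased = 43L,
                          mirnaLinBiased = 18L,
                          mirnaUnexpressed = 9L,
                          topMirnaFold = 4.38,
                          nDonors = 122L,
                          mafs = c(rs564398 = 0.40, rs2383208 = 0.30,
                                   rs10757283 = 0.45, rs10811661 = 0.35),
                          betaGenotype = 0.5,
                          assayNoiseSd = 1.0,
                          circCircR = 0.85,
                          circLinR = 0.63,
                          prolifIntercept = 2.2,
                          prolifSlope = 0.25,
                          prolifNoiseSd = 0.3,
                          nProliferationDonors = 45L,
                          nStimulationDonors = 83L,
                          nDiabetic = 10L,
                          nGenesGenomeWide = 1000L,
                          muLogTpm = 1.5, sdLogTpm = 1.2,
                          muLogJpm = -2.0, sdLogJpm = 1.6) {
  spec <- list(seed = as.integer(seed), nExons = as.integer(nExons),
               exonLengthRange = exonLengthRange,
               intronLengthRange = intronLengthRange,
               longIntrons = longIntrons, longIntronFactor = longIntronFactor,
               circles = circles, circFraction = circFraction,
               pRetainLinear = pRetainLinear,
               bsjCrossFraction = bsjCrossFraction,
               nSamples = as.integer(nSamples),
               readsPerSample = as.integer(readsPerSample),
               mappedPerJunctionRead = as.integer(mappedPerJunctionRead),
               segmentLength = as.integer(segmentLength),
               noiseJunctions = as.integer(noiseJunctions),
               nClones = as.integer(nClones),
               mirnaCircBiased = as.integer(mirnaCircBiased),
               mirnaLinBiased = as.integer(mirnaLinBiased),
               mirnaUnexpressed = as.integer(mirnaUnexpressed),
               topMirnaFold = topMirnaFold,
               nDonors = as.integer(nDonors), mafs = mafs,
               betaGenotype = betaGenotype, assayNoiseSd = assayNoiseSd,
               circCircR = circCircR, circLinR = circLinR,
               prolifIntercept = prolifIntercept, prolifSlope = prolifSlope,
               prolifNoiseSd = prolifNoiseSd,
               nProliferationDonors = as.integer(nProliferationDonors),
               nStimulationDonors = as.integer(nStimulationDonors),
               nDiabetic = as.integer(nDiabetic),
               nGenesGenomeWide = as.integer(nGenesGenomeWide),
               muLogTpm = muLogTpm, sdLogTpm = sdLogTpm,
               muLogJpm = muLogJpm, sdLogJpm = sdLogJpm)
  stopifnot(all(vapply(list(circFraction, pRetainLinear, bsjCrossFraction),
                       function(p) p >= 0 && p <= 1, logical(1L))))
  if (abs(sum(spec$circles$weight) - 1) > 1e-9)
    stop("circle weights must sum to 1")
  class(spec) <- "circletSpec"
  spec
}

#' @rdname syntheticSpec
#' @export
defaultCircles <- function() {
  data.frame(
    acceptor = c(5, 5, 5, 4, 2, 2, 4, 5, 6, 8, 13, 2, 6, 4, NA, 5, NA),
    donor    = c(7, 10, 16, 16, 7, 16, 7, 19, 10, 16, 16, 10, 20, 20, 7, NA, 16),
    acceptorIntron = c(rep(NA, 14), 3, NA, 11),
    donorIntron    = c(rep(NA, 15), 17, NA),
    weight = c(0.22, 0.13, 0.11, 0.09, 0.05, 0.05, 0.04, 0.04, 0.04, 0.03,
               0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.02))
}

# deterministic sub-seed per generator stage
.stageSeed <- function(seed, stage) {
  offsets <- c(gene = 11L, reads = 23L, cohort = 37L, qpcr = 41L,
               fractionation = 43L, genomewide = 47L, noise = 53L)
  as.integer((as.double(seed) * 1009 + offsets[[stage]]) %% 2147483629)
}

.randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# enumerate distinct seed-target words: "G" + 6 letters drawn from {A,C,T},
# so that targets can never arise from the {A,C} exon background and two
# planted words can never spawn a third (every match has exactly one G, at
# its first position)
.seedTargetWords <- function(n) {
  if (n > 3^6) stop("too many seed words requested")
  alph <- c("A", "C", "T")
  grid <- expand.grid(rep(list(alph), 6L), stringsAsFactors = FALSE)
  words <- apply(grid[seq_len(n), , drop = FALSE], 1L, paste, collapse = "")
  paste0("G", words)
}

#' Generate the synthetic gene: annotation, sequences and ground truth
#'
#' Builds a multi-exon plus-strand gene to the geometry in `spec`:
#' transcript models whose exon union is the planted meta-isoform; intron
#' sequences (random ACGT with canonical GT..AG ends) carrying two planted
#' inverted repeats — a 20-nt exact repeat between the intron upstream of
#' exon 2 and the intron downstream of exon 7 (alignment score 40) and a
#' 30-nt repeat with one internal mismatch between the exon-2 and exon-16
#' flanking introns (score 55), each insulated by mismatching flank guards
#' so the planted score is exact; exon sequences over a reduced {A,C}
#' background carrying miRNA seed-site plants at per-class densities (so
#' planted site counts are exact by construction); a Sanger clone table; and
#' the miRNA panel with expression values.
#'
#' @param spec a [syntheticSpec()] object.
#' @return list with elements `spec`, `meta` ([MetaIsoform-class]),
#'   `transcripts` (GRangesList), `genome` (`DNAStringSet`), `exonSeqs`,
#'   `intronSeqs`, `circles` (resolved genomic coordinates + weights),
#'   `clones`, `cloneExonTable`, `classification`, `mirnas`,
#'   `invertedRepeats`, and `chrom`.
#' @export
generateGene <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "circletSpec"))
  set.seed(.stageSeed(spec$seed, "gene"))
  n <- spec$nExons
  chrom <- "chrS"

  exLen <- sample(seq(spec$exonLengthRange[1L], spec$exonLengthRange[2L]),
                  n, replace = TRUE)
  inLen <- sample(seq(spec$intronLengthRange[1L], spec$intronLengthRange[2L]),
                  n - 1L, replace = TRUE)
  intronNames <- paste(seq_len(n - 1L), seq(2L, n), sep = "_")
  long <- intronNames %in% spec$longIntrons
  inLen[long] <- as.integer(round(inLen[long] * spec$longIntronFactor))

  flank <- 500L
  starts <- integer(n); ends <- integer(n)
  pos <- flank + 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + exLen[i] - 1L
    pos <- ends[i] + if (i < n) inLen[i] + 1L else 1L
  }
  exons <- GRanges(chrom, IRanges(starts, ends), strand = "+")
  mcols(exons)$exon_number <- seq_len(n)
  meta <- MetaIsoform("SYNGENE", exons)

  # transcripts whose exon union is exactly the meta-isoform
  mkTx <- function(idx, id, trimFirst = 0L) {
    gr <- exons[idx]
    if (trimFirst > 0L)
      gr[1L] <- GenomicRanges::resize(gr[1L], width(gr[1L]) - trimFirst,
                                      fix = "end")
    mcols(gr) <- NULL
    mcols(gr)$gene_id <- "SYNGENE"
    mcols(gr)$transcript_id <- id
    gr
  }
  transcripts <- GRangesList(
    tx1 = mkTx(seq_len(n), "tx1"),
    tx2 = mkTx(seq_len(min(10L, n)), "tx2"),
    tx3 = mkTx(seq(min(4L, n), min(16L, n)), "tx3", trimFirst = 50L))

  # resolve planted circle coordinates
  circ <- spec$circles
  introns <- metaIntrons(meta)
  accPos <- integer(nrow(circ)); donPos <- integer(nrow(circ))
  accLab <- character(nrow(circ)); donLab <- character(nrow(circ))
  for (i in seq_len(nrow(circ))) {
    if (!is.na(circ$acceptor[i])) {
      accPos[i] <- starts[circ$acceptor[i]]
      accLab[i] <- as.character(circ$acceptor[i])
    } else {
      k <- circ$acceptorIntron[i]
      itr <- introns[names(introns) == paste0(k, "_", k + 1L)]
      accPos[i] <- start(itr) + as.integer(floor(width(itr) / 3))
      accLab[i] <- paste0("between_", k, "_", k + 1L)
    }
    if (!is.na(circ$donor[i])) {
      donPos[i] <- ends[circ$donor[i]]
      donLab[i] <- as.character(circ$donor[i])
    } else {
      k <- circ$donorIntron[i]
      itr <- introns[names(introns) == paste0(k, "_", k + 1L)]
      donPos[i] <- start(itr) + as.integer(floor(2 * width(itr) / 3))
      donLab[i] <- paste0("between_", k, "_", k + 1L)
    }
  }
  circles <- data.frame(name = paste0(donLab, "-", accLab),
                        acceptor_label = accLab, donor_label = donLab,
                        acceptor_pos = accPos, donor_pos = donPos,
                        start = accPos, end = donPos,
                        weight = circ$weight)
  if (any(circles$start >= circles$end))
    stop("planted circle with acceptor not upstream of donor")

  # ---- Sanger clone design -------------------------------------------------
  validated <- cbind(a = c(5, 5, 5, 4, 2, 2, 4, 5, 6, 8),
                     d = c(7, 10, 16, 16, 7, 16, 7, 19, 10, 16),
                     count = c(20, 14, 12, 10, 6, 5, 5, 4, 4, 3))
  cloneOnly <- cbind(
    a = c(2, 2, 3, 5, 4, 6, 3,  2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5, 6, 6, 6, 7, 7, 8, 8),
    d = c(5, 6, 9, 8, 10, 16, 7, 8, 12, 6, 8, 12, 6, 8, 12, 11, 12, 13, 7, 8, 12, 9, 12, 9, 10),
    count = c(rep(2L, 7L), rep(1L, 18L)))
  cloneJx <- rbind(validated, cloneOnly)
  stopifnot(sum(cloneJx[, "count"]) == spec$nClones)
  clones <- data.frame(acceptor_exon = cloneJx[, "a"],
                       donor_exon = cloneJx[, "d"],
                       acceptor_pos = starts[cloneJx[, "a"]],
                       donor_pos = ends[cloneJx[, "d"]],
                       count = cloneJx[, "count"])
  # clone x exon presence (a clone spans its acceptor..donor exons)
  cloneExonTable <- do.call(rbind, lapply(seq_len(nrow(clones)), function(i) {
    row <- as.integer(seq_len(n) >= clones$acceptor_exon[i] &
                      seq_len(n) <= clones$donor_exon[i])
    matrix(rep(row, clones$count[i]), ncol = n, byrow = TRUE)
  }))
  colnames(cloneExonTable) <- as.character(seq_len(n))
  classification <- classifyExons(cloneExonTable)

  # ---- miRNA panel and seed-site planting ----------------------------------
  nCircB <- spec$mirnaCircBiased; nLinB <- spec$mirnaLinBiased
  nUnexp <- spec$mirnaUnexpressed
  nPanel <- nCircB + nLinB + nUnexp
  targets <- .seedTargetWords(nPanel)
  # miRNA 5'->3': position 1 arbitrary, positions 2-8 = revcomp(target)
  seedRC <- as.character(reverseComplement(DNAStringSet(targets)))
  mirSeq <- paste0("U", chartr("T", "U", seedRC),
                   vapply(seq_len(nPanel), function(i)
                     paste(sample(c("A", "C", "G", "U"), 13L, TRUE),
                           collapse = ""), character(1L)))
  mirId <- sprintf("synmiR-%03d", seq_len(nPanel))

  circExons <- as.integer(classification$exon[classification$class == "circular"])
  linExons <- as.integer(classification$exon[classification$class == "linear"])
  if (length(circExons) == 0L || length(linExons) == 0L)
    stop("clone design must yield both exon classes")
  lenC <- sum(exLen[circExons]); lenL <- sum(exLen[linExons])

  plantC <- integer(nPanel); plantL <- integer(nPanel)
  # top miRNA: fixed linear plant, circular plant targeting topMirnaFold
  plantL[1L] <- 10L
  plantC[1L] <- as.integer(round(spec$topMirnaFold * plantL[1L] * lenC / lenL))
  for (i in seq(2L, nCircB)) {
    plantL[i] <- sample(1:2, 1L)
    f <- runif(1L, 1.3, 2.2)
    minC <- floor(plantL[i] * lenC / lenL) + 1L
    plantC[i] <- max(as.integer(ceiling(f * plantL[i] * lenC / lenL)), minC)
  }
  for (i in seq(nCircB + 1L, nCircB + nLinB)) {
    plantC[i] <- sample(0:1, 1L)
    need <- if (plantC[i] == 0L) 1L else floor(plantC[i] * lenL / lenC) + 1L
    plantL[i] <- need + sample(0:2, 1L)
  }
  # expression: expressed strictly above 5 mean RPM, unexpressed at or below
  rpm <- matrix(0, nPanel, 3L)
  rpm[seq_len(nCircB + nLinB), ] <- 5 + matrix(
    stats::rexp((nCircB + nLinB) * 3L, rate = 1 / 20), ncol = 3L)
  if (nUnexp > 0L) {
    rpm[seq(nCircB + nLinB + 1L, nPanel), ] <-
      matrix(runif(nUnexp * 3L, 0, 4.5), ncol = 3L)
    rpm[nCircB + nLinB + 1L, ] <- c(5, 5, 5)   # boundary case: mean exactly 5
  }
  mirnas <- data.frame(mirna_id = mirId, sequence = mirSeq,
                       rpm1 = rpm[, 1L], rpm2 = rpm[, 2L], rpm3 = rpm[, 3L],
                       planted_circular = plantC, planted_linear = plantL,
                       direction = c(rep("circular", nCircB),
                                     rep("linear", nLinB),
                                     rep("unexpressed", nUnexp)))

  # lay planted sites into exon sequences: slots of 11 nt (4 spacer + 7 site)
  buildClassSeqs <- function(exonsIdx, counts) {
    sites <- rep(targets[seq_len(nPanel)], counts)
    if (length(sites) > 1L) sites <- sample(sites)
    cap <- pmax((exLen[exonsIdx] - 4L) %/% 11L, 0L)
    if (sum(cap) < length(sites))
      stop("planted miRNA sites exceed exon capacity; enlarge exons")
    assignment <- rep(exonsIdx, cap)[seq_along(sites)]
    seqs <- lapply(exonsIdx, function(e) {
      s <- sample(c("A", "C"), exLen[e], replace = TRUE)
      mine <- sites[assignment == e]
      for (k in seq_along(mine)) {
        at <- 4L + (k - 1L) * 11L + 1L
        s[at:(at + 6L)] <- strsplit(mine[k], "")[[1L]]
      }
      paste(s, collapse = "")
    })
    names(seqs) <- as.character(exonsIdx)
    seqs
  }
  exonSeqList <- c(buildClassSeqs(circExons, plantC),
                   buildClassSeqs(linExons, plantL))
  exonSeqList <- exonSeqList[as.character(seq_len(n))]
  exonSeqs <- DNAStringSet(unlist(exonSeqList))

  # ---- intron sequences with planted inverted repeats ----------------------
  intronSeqList <- lapply(seq_len(n - 1L), function(i) {
    s <- strsplit(.randSeq(inLen[i]), "")[[1L]]
    s[1:2] <- c("G", "T"); s[(length(s) - 1L):length(s)] <- c("A", "G")
    s
  })
  names(intronSeqList) <- intronNames

  plantRepeat <- function(nameA, nameB, len, mismatchAt = NA, offA, offB) {
    r <- strsplit(.randSeq(len), "")[[1L]]
    a <- intronSeqList[[nameA]]
    if (len + 6L + offA > length(a) - 8L || len + 6L + offB >
        length(intronSeqList[[nameB]]) - 8L)
      stop("planted repeat longer than host intron allows")
    ia <- offA + seq_len(len)
    a[ia] <- r
    a[c(ia[1L] - (3:1), ia[len] + (1:3))] <- "A"          # guard flanks in A
    intronSeqList[[nameA]] <<- a
    # work in revcomp space for B so the copy is a direct match
    b <- intronSeqList[[nameB]]
    brc <- rev(chartr("ACGT", "TGCA", b))
    r2 <- r
    if (!is.na(mismatchAt)) {
      old <- r2[mismatchAt]
      r2[mismatchAt] <- setdiff(c("A", "C", "G", "T"), old)[1L]
    }
    ib <- offB + seq_len(len)
    brc[ib] <- r2
    brc[c(ib[1L] - (3:1), ib[len] + (1:3))] <- "C"        # mismatch the guards
    b2 <- rev(chartr("ACGT", "TGCA", brc))
    b2[1:2] <- c("G", "T"); b2[(length(b2) - 1L):length(b2)] <- c("A", "G")
    intronSeqList[[nameB]] <<- b2
    list(startA = ia[1L], endA = ia[len], len = len)
  }
  ir1 <- plantRepeat("1_2", "7_8", 20L, mismatchAt = NA, offA = 40L, offB = 60L)
  ir2 <- plantRepeat("1_2", "16_17", 30L, mismatchAt = 15L, offA = 120L, offB = 90L)
  invertedRepeats <- data.frame(
    intronA = c("1_2", "1_2"), intronB = c("7_8", "16_17"),
    startA = c(ir1$startA, ir2$startA), endA = c(ir1$endA, ir2$endA),
    length = c(20L, 30L), mismatches = c(0L, 1L),
    expected_score = c(40, 55))

  intronSeqs <- DNAStringSet(vapply(intronSeqList, paste, "", collapse = ""))

  # assemble the chromosome
  pieces <- character(2L * n + 1L)
  pieces[1L] <- .randSeq(flank)
  for (i in seq_len(n)) {
    pieces[2L * i] <- as.character(exonSeqs[[i]])
    if (i < n) pieces[2L * i + 1L] <- as.character(intronSeqs[[i]])
  }
  pieces[2L * n + 1L] <- .randSeq(flank)
  genome <- DNAStringSet(paste(pieces[nchar(pieces) > 0L], collapse = ""))
  names(genome) <- chrom

  list(spec = spec, meta = meta, transcripts = transcripts, genome = genome,
       exonSeqs = exonSeqs, intronSeqs = intronSeqs, circles = circles,
       clones = clones, cloneExonTable = cloneExonTable,
       classification = classification, mirnas = mirnas,
       invertedRepeats = invertedRepeats, chrom = chrom,
       exonLengths = setNames(exLen, seq_len(n)))
}

#' Simulate segmented junction-read alignments under RNase R / mock design
#'
#' Emits two-segment read records per library: each sample starts from
#' `readsPerSample` nominal junction-spanning molecules of which a fraction
#' `circFraction` are circular. Under RNase R, linear molecules survive only
#' with probability `pRetainLinear` while circles always survive (so treated
#' libraries are smaller and raw linear-junction counts deplete by about
#' `pRetainLinear`, while library-size-normalised BSJ abundance is enriched
#' `1 / (f + (1 - f) p)`-fold). Circular reads cross their back-splice
#' junction with probability `bsjCrossFraction` (emitted with the donor-side
#' segment first in read order); all other reads are co-linear across an
#' ordinary splice junction. Per-library `mapped_reads` scales with the
#' realised junction-read total. Singleton cryptic noise junctions (one
#' read, one library) are appended.
#'
#' @param gene output of [generateGene()].
#' @param spec defaults to `gene$spec`.
#' @return list: `segments` (data.frame for [detectBsj()]), `libraries`
#'   (colData-style data.frame), `truth` (`bsjCounts` planted-junction x
#'   library tally of emitted BSJ reads, `linearCounts` per linear junction,
#'   and `noise` coordinates).
#' @export
simulateReads <- function(gene, spec = gene$spec) {
  set.seed(.stageSeed(spec$seed, "reads"))
  meta <- gene$meta
  ex <- metaExons(meta)
  n <- length(ex)
  chrom <- gene$chrom
  L <- spec$segmentLength
  circles <- gene$circles
  N <- spec$readsPerSample
  f <- spec$circFraction
  p <- spec$pRetainLinear
  q <- spec$bsjCrossFraction

  libs <- expand.grid(sample_id = paste0("S", seq_len(spec$nSamples)),
                      treatment = c("untreated", "rnase_r"),
                      stringsAsFactors = FALSE)
  libs$library <- paste(libs$sample_id, libs$treatment, sep = ".")
  libs$mapped_reads <- NA_real_

  bsjCounts <- matrix(0L, nrow(circles), nrow(libs),
                      dimnames = list(circles$name, libs$library))
  linearCounts <- matrix(0L, n - 1L, nrow(libs),
                         dimnames = list(paste(seq_len(n - 1L), seq(2L, n),
                                               sep = "_"), libs$library))
  # circle-internal linear junctions: consecutive exon pairs both within span
  circleJunctions <- lapply(seq_len(nrow(circles)), function(i) {
    js <- which(start(ex)[-n] >= circles$start[i] &
                end(ex)[-1L] <= circles$end[i])
    if (length(js) == 0L) NA_integer_ else js
  })

  allSeg <- vector("list", nrow(libs))
  readCounter <- 0L
  for (li in seq_len(nrow(libs))) {
    treated <- libs$treatment[li] == "rnase_r"
    nCirc <- rbinom(1L, N, f)
    nLin <- if (treated) rbinom(1L, N - nCirc, p) else N - nCirc
    nCross <- rbinom(1L, nCirc, q)
    perCircle <- as.integer(stats::rmultinom(1L, nCross, circles$weight))
    bsjCounts[, li] <- perCircle
    libs$mapped_reads[li] <- (nCirc + nLin) * spec$mappedPerJunctionRead

    # BSJ reads: donor-side segment first in read order
    ci <- rep(seq_len(nrow(circles)), perCircle)
    nb <- length(ci)
    bsjSeg <- if (nb > 0L) data.frame(
      read_id = rep(sprintf("r%07d", readCounter + seq_len(nb)), each = 2L),
      sample_id = libs$sample_id[li], treatment = libs$treatment[li],
      chrom = chrom,
      start = as.vector(rbind(circles$donor_pos[ci] - L + 1L,
                              circles$acceptor_pos[ci])),
      end = as.vector(rbind(circles$donor_pos[ci],
                            circles$acceptor_pos[ci] + L - 1L)),
      strand = "+",
      segment = rep(1:2, nb)) else NULL
    readCounter <- readCounter + nb

    # co-linear reads: circle-internal plus linear-molecule reads
    nInternal <- nCirc - nCross
    ciInt <- rep(seq_len(nrow(circles)),
                 as.integer(stats::rmultinom(1L, nInternal, circles$weight)))
    jInt <- vapply(ciInt, function(i) {
      js <- circleJunctions[[i]]
      if (length(js) == 1L && is.na(js[1L])) NA_integer_
      else if (length(js) == 1L) js else sample(js, 1L)
    }, integer(1L))
    jInt <- jInt[!is.na(jInt)]
    jLin <- sample(seq_len(n - 1L), nLin, replace = TRUE)
    j <- c(jInt, jLin)
    linearCounts[, li] <- tabulate(j, n - 1L)
    nc <- length(j)
    colSeg <- if (nc > 0L) data.frame(
      read_id = rep(sprintf("r%07d", readCounter + seq_len(nc)), each = 2L),
      sample_id = libs$sample_id[li], treatment = libs$treatment[li],
      chrom = chrom,
      start = as.vector(rbind(end(ex)[j] - L + 1L, start(ex)[j + 1L])),
      end = as.vector(rbind(end(ex)[j], start(ex)[j + 1L] + L - 1L)),
      strand = "+",
      segment = rep(1:2, nc)) else NULL
    readCounter <- readCounter + nc
    allSeg[[li]] <- rbind(bsjSeg, colSeg)
  }

  # cryptic singleton BSJs, one read in one random library each
  set.seed(.stageSeed(spec$seed, "noise"))
  introns <- metaIntrons(meta)
  noise <- NULL
  noiseSeg <- NULL
  if (spec$noiseJunctions > 0L && length(introns) >= 2L) {
    for (k in seq_len(spec$noiseJunctions)) {
      iA <- sample(seq_len(length(introns) - 1L), 1L)
      cand <- seq(iA + 1L, length(introns))
      iB <- cand[sample.int(length(cand), 1L)]
      aPos <- start(introns)[iA] + 5L + k
      dPos <- end(introns)[iB] - 5L - k
      li <- sample(nrow(libs), 1L)
      readCounter <- readCounter + 1L
      noiseSeg <- rbind(noiseSeg, data.frame(
        read_id = rep(sprintf("r%07d", readCounter), 2L),
        sample_id = libs$sample_id[li], treatment = libs$treatment[li],
        chrom = chrom,
        start = c(dPos - L + 1L, aPos), end = c(dPos, aPos + L - 1L),
        strand = "+", segment = 1:2))
      noise <- rbind(noise, data.frame(start = aPos, end = dPos,
                                       library = libs$library[li]))
    }
  }
  segments <- do.call(rbind, c(allSeg, list(noiseSeg)))
  rownames(segments) <- NULL
  list(segments = segments, libraries = libs,
       truth = list(bsjCounts = bsjCounts, linearCounts = linearCounts,
                    noise = noise))
}

#' Simulate the donor cohort: genotypes, qPCR expression and phenotypes
#'
#' Genotypes are binomial(2, MAF) allele-dosage draws per SNP. Expression is
#' a one-latent-factor model on the log2 scale: a shared transcription
#' factor drives the linear assay; circular assays load on a circular latent
#' correlated with it, giving circular-circular correlations near
#' `circCircR` and circular-linear correlations near `circLinR`; the
#' rs564398 dosage adds `betaGenotype` log2 units to every circular assay
#' (and hence to the circ/lin ratio), and circular assays sit 2 log2 units
#' above linear on average. The proliferation index (measured in the first
#' `nProliferationDonors` donors) decreases linearly in the log2 circ/lin
#' ratio; the stimulation index is independent of it.
#'
#' @param spec a [syntheticSpec()] object.
#' @return data.frame of donors with genotype dosages, log2 assay
#'   expression (`lin_1_2`, `circ_7_5`, `circ_10_5`, `circ_16_4`,
#'   `circ_16_5`, `circ_5_6`), `log2_circ_lin_ratio`, `circ_lin_ratio`,
#'   BrdU percentages and `proliferation_index`, `stimulation_index` and
#'   `diabetic`; generator parameters are attached as attribute `"truth"`.
#' @export
simulateCohort <- function(spec = syntheticSpec()) {
  set.seed(.stageSeed(spec$seed, "cohort"))
  n <- spec$nDonors
  dos <- vapply(spec$mafs, function(m) rbinom(n, 2L, m), integer(n))
  colnames(dos) <- names(spec$mafs)

  lam <- sqrt(spec$circCircR)
  alpha <- min(spec$circLinR / lam, 0.99)
  u <- rnorm(n); v <- rnorm(n)
  cc <- alpha * u + sqrt(1 - alpha^2) * v
  sd0 <- spec$assayNoiseSd
  g <- spec$betaGenotype * dos[, "rs564398"]
  muL <- -4; muC <- muL + 2
  lin <- muL + sd0 * u
  circAssay <- function() muC + sd0 * (lam * cc + sqrt(1 - lam^2) * rnorm(n)) + g
  circ75 <- circAssay(); circ105 <- circAssay()
  circ164 <- circAssay(); circ165 <- circAssay(); circ56 <- circAssay()

  logRatio <- circ56 - lin
  prolif <- pmax(spec$prolifIntercept - spec$prolifSlope * logRatio +
                   rnorm(n, 0, spec$prolifNoiseSd), 0.05)
  pct5 <- runif(n, 0.5, 2)
  pct15 <- prolif * pct5
  keepP <- seq_len(n) <= spec$nProliferationDonors
  prolif[!keepP] <- NA; pct5[!keepP] <- NA; pct15[!keepP] <- NA
  stim <- rlnorm(n, log(2), 0.4)
  stim[seq_len(n) > spec$nStimulationDonors] <- NA

  out <- data.frame(donor_id = sprintf("D%03d", seq_len(n)), dos,
                    lin_1_2 = lin, circ_7_5 = circ75, circ_10_5 = circ105,
                    circ_16_4 = circ164, circ_16_5 = circ165,
                    circ_5_6 = circ56,
                    log2_circ_lin_ratio = logRatio,
                    circ_lin_ratio = 2^logRatio,
                    pct_brdu_insulin_15mM = pct15,
                    pct_brdu_insulin_5mM = pct5,
                    proliferation_index = prolif,
                    stimulation_index = stim,
                    diabetic = seq_len(n) > n - spec$nDiabetic)
  attr(out, "truth") <- list(betaGenotype = spec$betaGenotype,
                             prolifSlope = spec$prolifSlope,
                             circCircR = spec$circCircR,
                             circLinR = spec$circLinR)
  out
}

#' Simulate RNase R qPCR retention replicates
#'
#' Circular assays retain near-full expression after digestion while linear
#' and housekeeping assays are strongly depleted.
#'
#' @param spec a [syntheticSpec()] object.
#' @param replicates qPCR replicates per assay (default 6).
#' @return data.frame: `assay`, `class`, `replicate`, `expr_untreated`,
#'   `expr_treated` (log2 expression), `retention_true`.
#' @export
simulateRnaseRQpcr <- function(spec = syntheticSpec(), replicates = 6L) {
  set.seed(.stageSeed(spec$seed, "qpcr"))
  assays <- data.frame(
    assay = c("circ_7_5", "circ_10_5", "circ_16_4", "circ_16_5", "circ_5_6",
              "lin_1_2", "ACTB", "GAPDH"),
    class = c(rep("circular", 5L), rep("linear", 3L)))
  out <- do.call(rbind, lapply(seq_len(nrow(assays)), function(i) {
    ret <- if (assays$class[i] == "circular") runif(replicates, 0.75, 1.05)
           else runif(replicates, 0.06, 0.15)
    unt <- rnorm(replicates, -3, 0.5)
    data.frame(assay = assays$assay[i], class = assays$class[i],
               replicate = seq_len(replicates),
               expr_untreated = unt,
               expr_treated = unt + log2(ret),
               retention_true = ret)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate subcellular fractionation qPCR
#'
#' Circular assays are planted at tenfold cytoplasmic excess, the linear
#' assay at parity, and a nuclear marker at tenfold nuclear excess.
#'
#' @param spec a [syntheticSpec()] object.
#' @param replicates replicates per assay (default 3).
#' @return data.frame: `assay`, `class`, `replicate`, `expr_cytoplasmic`,
#'   `expr_nuclear` (log2 expression).
#' @export
simulateFractionationQpcr <- function(spec = syntheticSpec(), replicates = 3L) {
  set.seed(.stageSeed(spec$seed, "fractionation"))
  assays <- data.frame(
    assay = c("circ_7_5", "circ_10_5", "circ_16_4", "circ_16_5", "circ_5_6",
              "lin_1_2", "GAPDH", "NEAT1"),
    class = c(rep("circular", 5L), "linear", "housekeeping", "nuclear_marker"),
    shift = c(rep(log2(10), 5L), 0, 0, -log2(10)))
  out <- do.call(rbind, lapply(seq_len(nrow(assays)), function(i) {
    nuc <- rnorm(replicates, -4, 0.4)
    data.frame(assay = assays$assay[i], class = assays$class[i],
               replicate = seq_len(replicates),
               expr_cytoplasmic = nuc + assays$shift[i] +
                 rnorm(replicates, 0, 0.15),
               expr_nuclear = nuc)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a genome-wide circular/linear abundance table
#'
#' Independent log-normal linear (TPM) and circular (JPM) abundances per
#' gene; because the ratio JPM/TPM inherits -log(TPM), the log-scale
#' spreads (`sdLogTpm`, `sdLogJpm`) set the expected Spearman correlation
#' between TPM and the ratio to about
#' `-sdLogTpm / sqrt(sdLogTpm^2 + sdLogJpm^2)` (-0.6 at the defaults). One
#' planted high-abundance circRNA host gene, `synCIRBP` (a synthetic
#' stand-in, not the real CIRBP locus), sits at the 97th JPM percentile.
#'
#' @param spec a [syntheticSpec()] object.
#' @return data.frame: `gene`, `tpm`, `jpm`, with the planted gene id in
#'   attribute `"plantedTop"`.
#' @export
simulateGenomeWide <- function(spec = syntheticSpec()) {
  set.seed(.stageSeed(spec$seed, "genomewide"))
  n <- spec$nGenesGenomeWide
  tpm <- exp(rnorm(n, spec$muLogTpm, spec$sdLogTpm))
  jpmv <- exp(rnorm(n, spec$muLogJpm, spec$sdLogJpm))
  out <- data.frame(gene = sprintf("gene%04d", seq_len(n)),
                    tpm = tpm, jpm = jpmv)
  planted <- data.frame(gene = "synCIRBP",
                        tpm = exp(spec$muLogTpm),
                        jpm = unname(quantile(jpmv, 0.97)))
  out <- rbind(out, planted)
  attr(out, "plantedTop") <- "synCIRBP"
  out
}

#' Write the synthetic dataset to disk
#'
#' Emits the transcript annotation as GTF, the chromosome as FASTA, read
#' segments / clone / miRNA / donor tables as TSV, and (when jsonlite is
#' installed) the ground truth as JSON.
#'
#' @param gene output of [generateGene()].
#' @param reads output of [simulateReads()] (optional).
#' @param cohort output of [simulateCohort()] (optional).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSyntheticData <- function(gene, reads = NULL, cohort = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tx <- unlist(gene$transcripts, use.names = FALSE)
  mcols(tx)$type <- "exon"
  mcols(tx)$source <- "circlet_synthetic"
  rtracklayer::export(tx, file.path(dir, "annotation.gtf"), format = "gtf")
  writeXStringSet(gene$genome, file.path(dir, "genome.fa"))
  wtsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wtsv(gene$clones, "clones.tsv")
  wtsv(gene$mirnas, "mirnas.tsv")
  if (!is.null(reads)) wtsv(reads$segments, "segments.tsv")
  if (!is.null(cohort)) wtsv(cohort, "donors.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- list(circles = gene$circles,
                  invertedRepeats = gene$invertedRepeats,
                  classification = gene$classification)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
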