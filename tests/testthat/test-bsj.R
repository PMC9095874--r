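mkMeta <- function(strand = "+") {
  buildMetaIsoform(data.frame(
    transcript_id = "t", chrom = "c", strand = strand,
    start = c(101, 301, 601, 901, 1201, 1501, 1801),
    end = c(200, 400, 700, 1000, 1300, 1600, 1900)), geneId = "g")
}

seg <- function(read, s1, e1, s2, e2, sample = "S1", treatment = "untreated",
                strand = "+") {
  data.frame(read_id = read, sample_id = sample, treatment = treatment,
             chrom = "c", start = c(s1, s2), end = c(e1, e2),
             strand = strand, segment = 1:2)
}

test_that("a donor-to-upstream-acceptor read yields one BSJ; co-linear reads none", {
  meta <- mkMeta()
  # read order: exon 7 donor side first, then exon 5 acceptor side
  backsplice <- seg("r1", 1841, 1900, 1201, 1260)
  colinear <- seg("r2", 141, 200, 301, 360)
  x <- detectBsj(rbind(backsplice, colinear), meta)
  expect_equal(nrow(x), 1L)
  rr <- rowRanges(x)
  expect_equal(start(rr), 1201)
  expect_equal(end(rr), 1900)
  expect_equal(mcols(rr)$pair, "7-5")
  expect_equal(mcols(rr)$acceptor_label, "5")
  expect_equal(unname(assay(x, "counts")[1, 1]), 1L)
})

test_that("minus-strand back-splicing is detected with swapped boundaries", {
  meta <- mkMeta("-")  # exon 1 is rightmost; donor of exon 2 at start 1501
  # transcriptionally downstream segment (genomically left) first in read order
  x <- detectBsj(seg("r1", 601, 660, 1541, 1600, strand = "-"), meta)
  expect_equal(nrow(x), 1L)
  rr <- rowRanges(x)
  expect_equal(start(rr), 601)   # donor boundary of exon 5 (genomic start)
  expect_equal(end(rr), 1600)    # acceptor boundary of exon 2 (genomic end)
  expect_equal(mcols(rr)$donor_label, "5")
  expect_equal(mcols(rr)$acceptor_label, "2")
})

test_that("malformed and >2-segment reads are skipped with notice", {
  meta <- mkMeta()
  bad <- seg("r1", 1841, 1900, 1260, 1201)      # end < start on segment 2
  expect_warning(x <- detectBsj(bad, meta), "malformed")
  expect_equal(nrow(x), 0L)

  three <- rbind(seg("r2", 1841, 1900, 1201, 1260),
                 data.frame(read_id = "r2", sample_id = "S1",
                            treatment = "untreated", chrom = "c", start = 301,
                            end = 360, strand = "+", segment = 3L))
  expect_message(x2 <- detectBsj(three, meta), ">2 segments")
  expect_equal(nrow(x2), 0L)
})

test_that("planted junctions are recovered exactly with zero false positives", {
  g <- fxGene()
  r <- fxReads()
  x <- fxBsj()
  keys <- paste(start(rowRanges(x)), end(rowRanges(x)))
  planted <- paste(g$circles$start, g$circles$end)
  noise <- paste(r$truth$noise$start, r$truth$noise$end)
  # every planted circle had >= 1 crossing read in this design
  expect_true(all(rowSums(r$truth$bsjCounts) >= 1))
  expect_true(all(planted %in% keys))
  expect_true(all(noise %in% keys))
  expect_true(all(keys %in% c(planted, noise)))   # zero false positives
  # per-library support equals the generator's emission tally
  counts <- assay(x, "counts")[match(planted, keys), colnames(r$truth$bsjCounts)]
  expect_equal(unname(as.matrix(counts)), unname(r$truth$bsjCounts))
})

test_that("high-confidence filter applies the or/and support rules monotonically", {
  meta <- mkMeta()
  reads <- rbind(
    seg("a1", 1841, 1900, 1201, 1260, sample = "S1"),  # 2 individuals, 1 read each
    seg("a2", 1841, 1900, 1201, 1260, sample = "S2"),
    seg("b1", 1541, 1600, 901, 960, sample = "S1"),    # 1 individual, 2 reads
    seg("b2", 1541, 1600, 901, 960, sample = "S1"),
    seg("c1", 1841, 1900, 301, 360, sample = "S2"))    # singleton
  x <- detectBsj(reads, meta)
  orKeep <- filterHighConfidence(x, "or")
  andKeep <- filterHighConfidence(x, "and")
  expect_equal(sort(mcols(rowRanges(orKeep))$pair), c("6-4", "7-5"))
  # 2 individuals with 1 read each also carries 2 total reads: passes "and";
  # the single-individual 2-read junction does not
  expect_equal(mcols(rowRanges(andKeep))$pair, "7-5")
  expect_true(all(rownames(andKeep) %in% rownames(orKeep)))
  expect_true(all(rownames(orKeep) %in% rownames(x)))
})

test_that("splice-site usage proportions are normalised marginals", {
  meta <- mkMeta()
  reads <- do.call(rbind, c(
    lapply(1:2, function(i) seg(paste0("p", i), 1841, 1900, 1201, 1260)),  # 7-5: 2
    lapply(1:3, function(i) seg(paste0("q", i), 1541, 1600, 1201, 1260)),  # 6-5: 3
    lapply(1:5, function(i) seg(paste0("s", i), 1841, 1900, 901, 960))))   # 7-4: 5
  x <- detectBsj(reads, meta)
  u <- spliceSiteUsage(x)
  expect_equal(sum(u$pairs$proportion), 1)
  expect_equal(sum(u$acceptorMarginal), 1)
  expect_equal(sum(u$donorMarginal), 1)
  expect_equal(unname(u$acceptorMarginal[["5"]]), 0.5)
  expect_equal(unname(u$donorMarginal[["7"]]), 0.7)
  # single-pair table gives 100%
  x1 <- detectBsj(seg("only", 1841, 1900, 1201, 1260), meta)
  expect_equal(spliceSiteUsage(x1)$pairs$proportion, 1)
})

test_that("treatment enrichment is the library-normalised read fold", {
  meta <- mkMeta()
  mk <- function(n, treatment) do.call(rbind, lapply(seq_len(n), function(i)
    seg(paste0(treatment, i), 1841, 1900, 1201, 1260, treatment = treatment)))
  reads <- rbind(mk(53, "rnase_r"), mk(20, "untreated"))
  x <- detectBsj(reads, meta, mappedReads = 1e6)
  expect_equal(treatmentEnrichment(x), 53 / 20)   # 2.65
  # identical counts -> 1
  x2 <- detectBsj(rbind(mk(7, "rnase_r"), mk(7, "untreated")), meta,
                  mappedReads = 1e6)
  expect_equal(treatmentEnrichment(x2), 1)
})

test_that("synthetic RNase R depletes linear junction reads by about pRetainLinear", {
  g <- fxGene()
  r <- fxReads()
  lc <- r$truth$linearCounts
  treated <- grepl("rnase_r", colnames(lc))
  # junctions beyond every planted circle span are purely linear
  pure <- c("20_21", "21_22")
  ratio <- sum(lc[pure, treated]) / sum(lc[pure, !treated])
  p <- g$spec$pRetainLinear
  se <- sqrt(1 / sum(lc[pure, treated]) + 1 / sum(lc[pure, !treated]))
  expect_lt(abs(ratio - p), 3 * se * p + 0.02)
})

test_that("clone validation fractions are set-overlap fractions", {
  g <- fxGene()
  hc <- filterHighConfidence(fxBsj())
  v <- validateAgainstClones(hc, g$clones)
  expect_equal(v$validatedFraction, 10 / 17)
  expect_equal(v$nClones, 35L)
  # identical sets -> 100%; disjoint -> 0%
  rr <- rowRanges(hc)
  self <- data.frame(acceptor_pos = mcols(rr)$acceptor_pos,
                     donor_pos = mcols(rr)$donor_pos)
  expect_equal(validateAgainstClones(hc, self)$validatedFraction, 1)
  far <- data.frame(acceptor_pos = self$acceptor_pos + 1000,
                    donor_pos = self$donor_pos + 1000)
  expect_equal(validateAgainstClones(hc, far)$validatedFraction, 0)
})

test_that("exon coverage folds separate circular from linear exons", {
  expect_equal(exonCoverageFold(10, 10, 1e6, 1e6), 1)
  expect_true(all(exonCoverageFold(c(0, 0), c(5, 9), 1e6, 1e6) < 1))

  g <- fxGene()
  r <- fxReads()
  cov <- countExonCoverage(r$segments, g$meta)
  treated <- grepl("rnase_r", colnames(cov))
  fold <- exonCoverageFold(rowSums(cov[, treated]), rowSums(cov[, !treated]),
                           sum(r$libraries$mapped_reads[treated]),
                           sum(r$libraries$mapped_reads[!treated]))
  circExon <- "6"    # internal to the dominant circles
  linExon <- "21"    # never circular
  expect_gt(fold[circExon], fold[linExon])
})

test_that("BSJ tables survive a CIRIquant-style TSV round trip", {
  g <- fxGene()
  hc <- filterHighConfidence(fxBsj())
  rr <- rowRanges(hc)
  counts <- assay(hc, "counts")
  long <- do.call(rbind, lapply(seq_len(nrow(hc)), function(i) {
    nz <- which(counts[i, ] > 0)
    data.frame(chrom = as.character(seqnames(rr))[i], start = start(rr)[i],
               end = end(rr)[i], strand = "+",
               sample_id = colData(hc)$sample_id[nz],
               treatment = colData(hc)$treatment[nz],
               count = counts[i, nz],
               adjusted_count = counts[i, nz] * 1.1,
               mapped_reads = colData(hc)$mapped_reads[nz])
  }))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readCiriquantTable(f, g$meta)
  expect_equal(nrow(back), nrow(hc))
  expect_equal(sum(assay(back, "counts")), sum(counts))
  expect_true("adjusted" %in% assayNames(back))
  expect_equal(sort(mcols(rowRanges(back))$pair), sort(mcols(rr)$pair))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeBsjBed(hc, bed)
  tab <- read.delim(bed)
  expect_equal(nrow(tab), nrow(hc))
  expect_equal(sum(tab$score), sum(counts))
})
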