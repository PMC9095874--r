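test_that("PWM log-odds scoring: uniform model scores 0, informative columns add log2 odds", {
  # uniform 1-column model
  uni <- trainSpliceSitePwm(c("A", "C", "G", "T"), pseudocount = 0)
  for (b in c("A", "C", "G", "T")) expect_equal(scoreSpliceSite(b, uni), 0)
  # P(G) = 1 at column 1, uniform at column 2 -> score log2(4) = 2
  inf <- trainSpliceSitePwm(c("GA", "GC", "GG", "GT"), pseudocount = 0)
  expect_equal(scoreSpliceSite("GA", inf), 2)
  expect_equal(scoreSpliceSite("GC", inf), 2)
  # N contributes nothing
  expect_equal(scoreSpliceSite("GN", inf), 2)
  expect_error(scoreSpliceSite("GAT", inf), "length")
  expect_error(scoreSpliceSite("GX", inf), "ACGTN")
})

test_that("a canonical-donor PWM ranks GT windows above any non-GT window", {
  donors <- c("CAGGTAAGT", "AAGGTGAGT", "CAGGTAAGA", "TCGGTAAGT",
              "CAGGTGAGT", "GAGGTAAGT")
  pwm <- trainSpliceSitePwm(donors)
  gtScore <- scoreSpliceSite("CAGGTAAGT", pwm)
  for (sub in c("CAGCTAAGT", "CAGATAAGT", "CAGTTAAGT",
                "CAGGCAAGT", "CAGGAAAGT", "CAGGGAAGT"))
    expect_lt(scoreSpliceSite(sub, pwm), gtScore)
})

test_that("maxEnt-style score tables are looked up directly", {
  tab <- maxEntModel(c(GTA = 1.5, GTC = -0.25))
  expect_equal(scoreSpliceSite("GTC", tab), -0.25)
  expect_error(scoreSpliceSite("AAA", tab), "absent")
  expect_error(maxEntModel(c(1, 2)), "named")
})

test_that("splice-site windows have the documented geometry", {
  g <- fxGene()
  w <- spliceSiteWindows(g$meta, g$genome)
  expect_true(all(nchar(w$donor) == 9))
  expect_true(all(nchar(w$acceptor) == 23))
  # intron starts with GT -> donor window positions 4-5; ends AG -> acceptor 19-20
  expect_true(all(substr(w$donor[as.character(1:21)], 4, 5) == "GT"))
  expect_true(all(substr(w$acceptor[as.character(2:22)], 19, 20) == "AG"))
})

test_that("bootstrap group test: constants give 1, strong shifts give small p, swap complements", {
  expect_equal(bootstrapScoreTest(rep(2, 5), rep(2, 5), reps = 500, seed = 1), 1)
  set.seed(3)
  a <- rnorm(10) - 5; b <- rnorm(10)
  p <- bootstrapScoreTest(a, b, reps = 10000, seed = 5, alternative = "A_less")
  expect_lte(p, 0.01)
  expect_gt(p, 0)
  p1 <- bootstrapScoreTest(a + 4.7, b, reps = 4000, seed = 6, "A_less")
  p2 <- bootstrapScoreTest(b, a + 4.7, reps = 4000, seed = 7, "A_less")
  expect_lt(abs(p1 + p2 - 1), 0.05)
  expect_warning(bootstrapScoreTest(a, b, reps = 50, seed = 1), "100")
})

test_that("intron length table groups by role and conserves intron count", {
  g <- fxGene()
  roles <- setNames(rep("none", 22), 1:22)
  roles[c("2", "4", "5")] <- "3p"; roles[c("7", "10", "16")] <- "5p"
  tab <- intronLengthTable(g$meta, roles)
  expect_equal(nrow(tab), 22)
  # every intron appears exactly once as upstream and once as downstream
  expect_equal(sort(tab$upstream_length[!is.na(tab$upstream_length)]),
               sort(tab$downstream_length[!is.na(tab$downstream_length)]))
  expect_equal(sum(!is.na(tab$upstream_length)), 21)
  # planted long introns flank the 3p exons 2 and 4 (upstream) and donor 16
  med3p <- median(tab$upstream_length[tab$role == "3p" & tab$exon %in% c(2, 4)])
  medNone <- median(tab$upstream_length[tab$role == "none"], na.rm = TRUE)
  expect_gt(med3p, medNone)

  two <- buildMetaIsoform(data.frame(transcript_id = "t", chrom = "c",
                                     strand = "+", start = c(1, 201),
                                     end = c(100, 300)), geneId = "g")
  t2 <- intronLengthTable(two)
  expect_equal(t2$downstream_length, c(100L, NA))
})

test_that("planted inverted repeats score exactly as constructed", {
  g <- fxGene()
  ir <- g$invertedRepeats
  h1 <- findComplementaryRegions(as.character(g$intronSeqs[[ir$intronA[1]]]),
                                 as.character(g$intronSeqs[[ir$intronB[1]]]))
  # 20-nt exact repeat: score 20 * 2 = 40, alignment length 20
  expect_true(any(h1$score == 40 & h1$length == 20 &
                  h1$startA == ir$startA[1] & h1$endA == ir$endA[1]))
  h2 <- findComplementaryRegions(as.character(g$intronSeqs[[ir$intronA[2]]]),
                                 as.character(g$intronSeqs[[ir$intronB[2]]]))
  # 30-nt repeat with one internal mismatch: 29 * 2 - 3 = 55
  expect_true(any(h2$score == 55 & h2$length == 30))
})

test_that("complementarity search equals the Smith-Waterman oracle on pairs <= 300 nt", {
  set.seed(21)
  for (rep in 1:12) {
    core <- randDna(sample(12:30, 1))
    a <- paste0(randDna(sample(40:120, 1)), core, randDna(sample(40:120, 1)))
    brc <- paste0(randDna(sample(40:120, 1)), core, randDna(sample(40:120, 1)))
    b <- as.character(reverseComplement(DNAString(brc)))
    hits <- findComplementaryRegions(a, b)
    oracle <- swOracleScore(a, b)
    if (oracle > 25) {
      expect_gt(nrow(hits), 0)
      expect_equal(max(hits$score), oracle)
    } else {
      expect_true(nrow(hits) == 0 || max(hits$score) <= oracle)
    }
  }
})

test_that("random dissimilar 500-mers yield no hits and the oracle agrees", {
  set.seed(33)
  for (rep in 1:5) {
    a <- randDna(500); b <- randDna(500)
    hits <- findComplementaryRegions(a, b)
    expect_equal(nrow(hits), 0)
    expect_lte(swOracleScore(a, b), 25)
  }
})

test_that("hit score multisets are reflection-symmetric", {
  g <- fxGene()
  a <- as.character(g$intronSeqs[["1_2"]])
  b <- as.character(g$intronSeqs[["16_17"]])
  expect_equal(sort(findComplementaryRegions(a, b)$score),
               sort(findComplementaryRegions(b, a)$score))
})

test_that("short sequences warn and return no hits", {
  expect_warning(h <- findComplementaryRegions("ACGT", "ACGTACGTAC"),
                 "wordSize")
  expect_equal(nrow(h), 0)
})

test_that("random pairing null is seeded, excludes observed pairs and errors when exhausted", {
  uni <- expand.grid(a = 1:4, b = 1:4)
  obs <- data.frame(a = c(1, 2), b = c(2, 3))
  s1 <- randomPairingNull(obs, uni, 5, seed = 9)
  s2 <- randomPairingNull(obs, uni, 5, seed = 9)
  expect_identical(s1, s2)
  expect_false(any(paste(s1$a, s1$b) %in% paste(obs$a, obs$b)))
  # n equal to the complement size returns exactly the complement
  all14 <- randomPairingNull(obs, uni, 14, seed = 1)
  expect_equal(nrow(all14), 14)
  expect_error(randomPairingNull(obs, uni, 15, seed = 1), "available")
  expect_error(randomPairingNull(uni, uni, 1), "no non-occurring")
})

test_that("repeat overlap indicators match a per-base scan and Fisher matches the hypergeometric oracle", {
  set.seed(5)
  targets <- GRanges("c", IRanges(seq(1, 1000, 100), width = 50))
  others <- GRanges("c", IRanges(seq(2000, 2900, 100), width = 50))
  # no repeats anywhere -> p = 1
  expect_equal(repeatOverlapEnrichment(targets, others, GRanges())$p, 1)
  # repeats covering all targets, none of the others
  reps <- GRanges("c", IRanges(seq(1, 1000, 100), width = 10))
  r <- repeatOverlapEnrichment(targets, others, reps)
  expect_equal(r$p, stats::dhyper(10, 10, 10, 10) * 2)  # 2/C(20,10) two-sided
  expect_true(all(r$targetOverlap) && !any(r$otherOverlap))
  # indicator equals brute-force per-base comparison on random intervals
  regions <- GRanges("c", IRanges(sample(1:500, 20), width = sample(5:40, 20, TRUE)))
  rep2 <- GRanges("c", IRanges(sample(1:500, 8), width = sample(3:25, 8, TRUE)))
  got <- repeatOverlapEnrichment(regions, regions, rep2)$targetOverlap
  repBases <- unique(unlist(lapply(seq_along(rep2), function(i)
    start(rep2)[i]:end(rep2)[i])))
  want <- vapply(seq_along(regions), function(i)
    any((start(regions)[i]:end(regions)[i]) %in% repBases), logical(1))
  expect_equal(got, want)
})

test_that("intron halves partition with the proximal side taking the odd base", {
  i100 <- IRanges(1, 100)
  h <- splitIntronRegions(i100, "acceptor_3ss")
  expect_equal(width(h$proximal), 50)
  expect_equal(width(h$distal), 50)
  expect_equal(start(h$proximal), 51)    # acceptor side = right end on +
  i101 <- IRanges(1, 101)
  h2 <- splitIntronRegions(i101, "donor_5ss")
  expect_equal(width(h2$proximal), 51)
  expect_equal(start(h2$proximal), 1)    # donor side = left end on +
  # partition: disjoint, union = intron
  expect_equal(sort(c(start(h2$proximal), start(h2$distal))), c(1, 52))
  expect_equal(max(end(h2$proximal), end(h2$distal)), 101)
  # strand-awareness: on '-', the acceptor sits at the genomic left end
  gi <- GRanges("c", IRanges(1, 100), strand = "-")
  hg <- splitIntronRegions(gi, "acceptor_3ss")
  expect_equal(start(hg$proximal), 1)
  expect_error(splitIntronRegions(IRanges(1, 1), "donor_5ss"), ">= 2")
})

test_that("motif occurrence handles IUPAC codes and matches the hypergeometric oracle", {
  # "RY" matches exactly {AC, AT, GC, GT}
  hits <- vcountPattern("RY", DNAStringSet(c("AC", "AT", "GC", "GT", "AA",
                                             "CA", "TT", "CG")), fixed = FALSE)
  expect_equal(hits > 0, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  expect_equal(motifOccurrence("ACGT", "ACGT", "GGGG")$percentFg, 100)
  fg <- DNAStringSet(rep("TTACGTTT", 5))
  bg <- DNAStringSet(rep("TTTTTTTT", 5))
  r <- motifOccurrence("ACGT", fg, bg)
  expect_equal(r$percentFg, 100)
  expect_equal(r$percentBg, 0)
  # one-sided Fisher on 5/5 vs 0/5 presence = 1 / C(10,5)
  expect_equal(r$fisherP, 1 / choose(10, 5))
  expect_warning(motifOccurrence("NNN", fg, bg), "degenerate")
})
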