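# Shared fixtures, generated once per test run from the default synthetic
# study conditions (seed 1), plus independent oracles used across files.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(Biostrings)
})

.fx <- new.env(parent = emptyenv())

fxGene <- function() {
  if (is.null(.fx$gene)) .fx$gene <- generateGene(syntheticSpec())
  .fx$gene
}

fxReads <- function() {
  if (is.null(.fx$reads)) .fx$reads <- simulateReads(fxGene())
  .fx$reads
}

fxBsj <- function() {
  if (is.null(.fx$bsj)) {
    r <- fxReads()
    .fx$bsj <- suppressMessages(detectBsj(
      r$segments, fxGene()$meta,
      mappedReads = setNames(r$libraries$mapped_reads, r$libraries$library)))
  }
  .fx$bsj
}

fxCohort <- function() {
  if (is.null(.fx$cohort)) .fx$cohort <- simulateCohort(syntheticSpec())
  .fx$cohort
}

# independent affine-gap local alignment oracle (never the implementation)
swOracleScore <- function(a, b, reward = 2, penalty = -3,
                          gapOpen = 5, gapExt = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = reward,
                                                  mismatch = penalty,
                                                  baseOnly = TRUE)
  brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  pa <- Biostrings::pairwiseAlignment(a, brc, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExt)
  Biostrings::score(pa)
}

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# brute-force interval-union length by per-base occupancy
occupancyUnionLength <- function(starts, ends) {
  occ <- logical(max(ends))
  for (i in seq_along(starts)) occ[starts[i]:ends[i]] <- TRUE
  sum(occ)
}
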