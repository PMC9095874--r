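#' Classify meta-exons as circular or linear from clone evidence
#'
#' An exon is called circular when it appears in at least `threshold`
#' (default 10%) of the Sanger-sequenced clones; all other exons are called
#' linear (i.e. predominantly restricted to linear isoforms).
#'
#' @param cloneTable clones x exons logical/0-1 matrix or data.frame of exon
#'   presence (columns named by exon number).
#' @param threshold clone-fraction cutoff (default 0.10; the comparison is
#'   `>=`).
#' @return data.frame: `exon`, `cloneFraction`, `class`.
#' @export
classifyExons <- function(cloneTable, threshold = 0.10) {
  m <- as.matrix(cloneTable)
  if (nrow(m) < 1L) stop("at least one clone required")
  frac <- colMeans(m > 0)
  data.frame(exon = colnames(m),
             cloneFraction = unname(frac),
             class = ifelse(frac >= threshold, "circular", "linear"))
}

#' Filter miRNAs by expression
#'
#' Keeps miRNAs whose mean expression across the supplied datasets is
#' strictly greater than `minMeanRpm` reads per million (default 5; a mean
#' of exactly 5 is excluded).
#'
#' @param records data.frame with `mirna_id` and one or more `rpm*` columns
#'   (any columns matching `^rpm`), or with an `rpm` matrix-like set of
#'   numeric columns passed via `rpmColumns`.
#' @param minMeanRpm strict lower bound on the mean RPM.
#' @param rpmColumns optional explicit column names holding RPM values.
#' @return the filtered data.frame, with a `mean_rpm` column appended.
#' @export
filterExpressedMirnas <- function(records, minMeanRpm = 5, rpmColumns = NULL) {
  if (is.null(rpmColumns))
    rpmColumns <- grep("^rpm", names(records), value = TRUE)
  if (length(rpmColumns) == 0L) stop("no RPM columns found")
  mu <- rowMeans(as.matrix(records[, rpmColumns, drop = FALSE]))
  out <- records[mu > minMeanRpm, , drop = FALSE]
  out$mean_rpm <- mu[mu > minMeanRpm]
  rownames(out) <- NULL
  out
}

#' Seed-complementary target site of a miRNA
#'
#' The canonical seed match types: the target site is the exonic sequence
#' (5'->3') complementary to miRNA positions 2-8 (`"7mer-m8"`), positions
#' 2-7 (`"6mer"`), positions 2-7 plus an `A` opposite position 1
#' (`"7mer-A1"`), or positions 2-8 plus that `A` (`"8mer"`).
#'
#' @param mirnaSeq miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param type seed-match type.
#' @return the target DNA sequence to search for on the exon sense strand.
#' @examples
#' seedTarget("UGAGGUAGUAGGUUGUAUAGUU")   # let-7: "CTACCTC"
#' @export
seedTarget <- function(mirnaSeq, type = c("7mer-m8", "6mer", "7mer-A1", "8mer")) {
  type <- match.arg(type)
  s <- chartr("Uu", "Tt", toupper(as.character(mirnaSeq)))
  if (nchar(s) < 8L) stop("miRNA must be at least 8 nt")
  last <- if (type %in% c("7mer-m8", "8mer")) 8L else 7L
  seed <- substr(s, 2L, last)
  if (!grepl("^[ACGT]+$", seed))
    stop("ambiguous base in seed region: ", seed)
  core <- as.character(reverseComplement(DNAString(seed)))
  if (type %in% c("7mer-A1", "8mer")) paste0(core, "A") else core
}

#' Count seed-complementary sites per exon
#'
#' Counts occurrences of the seed target ([seedTarget()]) in each exon's
#' sense-strand sequence; overlapping matches are counted at distinct start
#' positions.
#'
#' @param mirnaSeq miRNA sequence 5'->3'.
#' @param exonSequences named `DNAStringSet` or character vector of exon
#'   sense-strand sequences.
#' @param type seed-match type (default `"7mer-m8"`).
#' @return named integer vector of site counts per exon.
#' @export
countSeedSites <- function(mirnaSeq, exonSequences, type = "7mer-m8") {
  target <- seedTarget(mirnaSeq, type)
  x <- DNAStringSet(exonSequences)
  setNames(vcountPattern(target, x, fixed = TRUE), names(x))
}

#' Length-normalised miRNA site density by exon class
#'
#' Aggregates per-exon site counts into the circular and linear exon
#' classes, normalises by each class's total exon length (sites per kb) and
#' reports the circular/linear density fold per miRNA, plus how many miRNAs
#' have a higher density in each class.
#'
#' @param siteCounts miRNAs x exons matrix of site counts (columns matching
#'   `classification$exon`).
#' @param classification output of [classifyExons()].
#' @param exonLengths named lengths (nt) of the same exons.
#' @return data.frame per miRNA (`mirna_id`, `sites_circular`,
#'   `sites_linear`, `density_circular`, `density_linear`, `fold`) with a
#'   `summary` attribute: `list(nMoreCircular, nMoreLinear, lengthCircular,
#'   lengthLinear)`. Zero linear sites with circular sites present give an
#'   `Inf` fold sentinel.
#' @export
siteDensityComparison <- function(siteCounts, classification, exonLengths) {
  m <- as.matrix(siteCounts)
  exons <- as.character(classification$exon)
  if (!all(colnames(m) %in% exons))
    stop("siteCounts columns must all be classified exons")
  if (!all(colnames(m) %in% names(exonLengths)))
    stop("every exon needs a length")
  cls <- setNames(classification$class, exons)[colnames(m)]
  lenC <- sum(exonLengths[colnames(m)[cls == "circular"]])
  lenL <- sum(exonLengths[colnames(m)[cls == "linear"]])
  if (lenC == 0 || lenL == 0)
    stop("a class with zero total exon length cannot be normalised")
  sC <- rowSums(m[, cls == "circular", drop = FALSE])
  sL <- rowSums(m[, cls == "linear", drop = FALSE])
  dC <- sC / (lenC / 1000)
  dL <- sL / (lenL / 1000)
  fold <- ifelse(sC == 0 & sL == 0, NaN, ifelse(dL == 0, Inf, dC / dL))
  out <- data.frame(mirna_id = rownames(m),
                    sites_circular = unname(sC), sites_linear = unname(sL),
                    density_circular = unname(dC), density_linear = unname(dL),
                    fold = unname(fold))
  attr(out, "summary") <- list(nMoreCircular = sum(dC > dL),
                               nMoreLinear = sum(dL > dC),
                               lengthCircular = unname(lenC),
                               lengthLinear = unname(lenL))
  out
}
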