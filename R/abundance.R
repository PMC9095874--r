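#' Junctions per million mapped reads (JPM)
#'
#' Circular abundance unit: each BSJ-crossing read is evidence for exactly
#' one circRNA molecule, so circular expression is counted as BSJ reads per
#' million mapped reads, `jpm = reads * 1e6 / mapped`. The identity
#' `sum(jpm * mapped / 1e6) == total BSJ reads` holds exactly.
#'
#' @param bsjReads BSJ read count(s).
#' @param mappedReads mapped-read total(s) of the library; must be > 0.
#' @return JPM value(s).
#' @examples
#' jpm(50, 1e7)   # 5
#' @export
jpm <- function(bsjReads, mappedReads) {
  if (any(mappedReads <= 0)) stop("mappedReads must be positive")
  bsjReads * 1e6 / mappedReads
}

#' Per-gene circular/linear abundance ratios
#'
#' Divides each gene's summed BSJ abundance (JPM) by its linear expression
#' (TPM). Genes with zero TPM but positive JPM get an `Inf` sentinel and are
#' retained flagged; genes at or below `tpmThreshold` are flagged as not
#' expressed.
#'
#' @param jpmByGene named numeric vector (or data.frame with `gene`, `jpm`)
#'   of per-gene summed circular JPM.
#' @param tpmByGene named numeric vector (or data.frame with `gene`, `tpm`).
#' @param tpmThreshold linear-expression threshold for the `expressed` flag
#'   (default 5 TPM).
#' @return data.frame: `gene`, `jpm`, `tpm`, `ratio`, `expressed`, `flagged`.
#' @export
circLinearRatio <- function(jpmByGene, tpmByGene, tpmThreshold = 5) {
  if (is.data.frame(jpmByGene)) jpmByGene <- setNames(jpmByGene$jpm, jpmByGene$gene)
  if (is.data.frame(tpmByGene)) tpmByGene <- setNames(tpmByGene$tpm, tpmByGene$gene)
  genes <- intersect(names(jpmByGene), names(tpmByGene))
  if (length(genes) == 0L) stop("no shared gene identifiers")
  j <- unname(jpmByGene[genes]); t <- unname(tpmByGene[genes])
  if (any(j < 0) || any(t < 0)) stop("negative JPM/TPM")
  ratio <- ifelse(j == 0, 0, ifelse(t == 0, Inf, j / t))
  data.frame(gene = genes, jpm = j, tpm = t, ratio = ratio,
             expressed = t > tpmThreshold,
             flagged = t == 0 & j > 0)
}

#' qPCR relative expression on the log2 scale
#'
#' Relative expression from cycle thresholds, normalised to the mean of the
#' endogenous reference assays: `-(ctTarget - mean(ctRefs))`. The sign is
#' chosen so that more template (a lower Ct) gives a higher value; one
#' template doubling adds one log2 unit.
#'
#' @param ctTarget Ct of the target assay (vectorised over samples).
#' @param ctRefs numeric vector (one sample) or matrix/data.frame (rows =
#'   samples) of reference-assay Cts.
#' @return log2-scale relative expression.
#' @export
qpcrExpression <- function(ctTarget, ctRefs) {
  if (is.null(ctRefs) || length(ctRefs) == 0L) stop("empty reference list")
  refMean <- if (is.matrix(ctRefs) || is.data.frame(ctRefs))
    rowMeans(as.matrix(ctRefs)) else mean(ctRefs)
  if (any(!is.finite(ctTarget)) || any(!is.finite(refMean)))
    stop("Ct values must be finite")
  -(ctTarget - refMean)
}

#' Relative retention after RNase R digestion
#'
#' Treated/untreated retention ratio per assay. Circular species resist the
#' 3'->5' exonuclease (retention near 1) while linear transcripts are
#' depleted. Inputs must be on the linear scale; set `log2Input = TRUE` for
#' log2 expression values (differences are then exponentiated).
#'
#' @param exprTreated,exprUntreated per-assay expression after and without
#'   RNase R.
#' @param log2Input are the inputs log2-scale expression values?
#' @return retention ratio(s).
#' @export
rnaseRDepletion <- function(exprTreated, exprUntreated, log2Input = FALSE) {
  if (log2Input) return(2^(exprTreated - exprUntreated))
  if (any(exprUntreated == 0)) stop("zero untreated expression")
  exprTreated / exprUntreated
}

#' Cytoplasmic/nuclear abundance ratio
#'
#' Per-assay compartment ratio from log2 expression (ratio = 2^(cyto - nuc))
#' or from linear-scale values. Assays missing either compartment are
#' skipped with a warning.
#'
#' @param exprCytoplasmic,exprNuclear named per-assay expression values.
#' @param log2Input are the inputs log2-scale (default TRUE, the qPCR
#'   convention of [qpcrExpression()])?
#' @return named ratio vector over assays present in both compartments.
#' @export
compartmentRatio <- function(exprCytoplasmic, exprNuclear, log2Input = TRUE) {
  if (!is.null(names(exprCytoplasmic)) && !is.null(names(exprNuclear))) {
    shared <- intersect(names(exprCytoplasmic), names(exprNuclear))
    dropped <- setdiff(union(names(exprCytoplasmic), names(exprNuclear)), shared)
    if (length(dropped))
      warning("assay(s) missing a compartment skipped: ",
              paste(dropped, collapse = ", "))
    exprCytoplasmic <- exprCytoplasmic[shared]
    exprNuclear <- exprNuclear[shared]
  }
  if (log2Input) 2^(exprCytoplasmic - exprNuclear)
  else exprCytoplasmic / exprNuclear
}

#' Pairwise correlation matrix of expression features
#'
#' Symmetric correlation matrix with unit diagonal across the feature
#' columns of an expression table, using pairwise-complete observations.
#' Constant features give `NA` entries and a warning rather than a silent
#' zero.
#'
#' @param table samples x features matrix or data.frame.
#' @param method `"pearson"` or `"spearman"`.
#' @param scale `"linear"` (use values as-is) or `"log"` (log2-transform
#'   positive values first; non-positive values become `NA`).
#' @return features x features correlation matrix.
#' @export
correlationMatrix <- function(table, method = c("pearson", "spearman"),
                              scale = c("linear", "log")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  m <- as.matrix(table)
  if (scale == "log") {
    if (any(m <= 0, na.rm = TRUE)) {
      warning("non-positive values set to NA before log transform")
      m[m <= 0] <- NA
    }
    m <- log2(m)
  }
  nObs <- crossprod(!is.na(m))
  if (any(nObs[upper.tri(nObs)] < 3L))
    warning("some feature pairs have fewer than 3 complete observations")
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("constant feature(s): ",
            paste(colnames(m)[which(sds == 0)], collapse = ", "),
            " produce undefined correlations (NA)")
  cm <- suppressWarnings(cor(m, use = "pairwise.complete.obs", method = method))
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}

#' Two-group location test
#'
#' Two-sided by default; Welch t or exact-where-possible Mann-Whitney
#' (Wilcoxon rank-sum). A t test on two degenerate (zero-variance) groups is
#' refused with a pointer to the rank test.
#'
#' @param groupA,groupB numeric vectors (each of length >= 2).
#' @param test `"t"` or `"mann_whitney"`.
#' @param alternative passed to the underlying test (two.sided default).
#' @return list with `statistic`, `p`, `test`, `alternative`.
#' @export
groupTest <- function(groupA, groupB, test = c("t", "mann_whitney"),
                      alternative = c("two.sided", "less", "greater")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (test == "t") {
    if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0)
      stop("degenerate variance in both groups; use test = 'mann_whitney'")
    fit <- t.test(groupA, groupB, alternative = alternative)
  } else {
    fit <- suppressWarnings(wilcox.test(groupA, groupB, alternative = alternative))
  }
  list(statistic = unname(fit$statistic), p = fit$p.value,
       test = test, alternative = alternative)
}

#' Iterative Fisher-exact gene set enrichment
#'
#' Greedy enrichment that avoids reporting overlapping gene sets: in each
#' round every term is tested by one-sided Fisher exact test
#' (query-vs-background membership), p-values are Benjamini-Hochberg
#' adjusted across the terms still in play, and the single most significant
#' term with adjusted p below `alpha` is accepted (ties broken by raw p,
#' then lexicographically). Its genes are then removed from both the query
#' and the background and the loop repeats until nothing reaches `alpha`.
#'
#' @param queryGenes character vector, a subset of `background`.
#' @param termGenes named list of character vectors (term -> genes).
#' @param background character vector of all eligible genes.
#' @param alpha adjusted-p acceptance threshold (default 0.05).
#' @return data.frame of accepted terms in acceptance order: `term`,
#'   `overlap`, `querySize`, `termSize`, `backgroundSize`, `pRaw`,
#'   `pAdjusted`.
#' @export
iterativeEnrichment <- function(queryGenes, termGenes, background,
                                alpha = 0.05) {
  if (!all(queryGenes %in% background))
    stop("queryGenes must be a subset of background")
  out <- list()
  query <- unique(queryGenes)
  bg <- unique(background)
  terms <- lapply(termGenes, unique)
  while (length(query) > 0L && length(terms) > 0L) {
    res <- vapply(terms, function(g) {
      g <- intersect(g, bg)
      a <- length(intersect(query, g))
      b <- length(query) - a
      c_ <- length(g) - a
      d <- length(bg) - length(query) - c_
      p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L),
                       alternative = "greater")$p.value
      c(p = p, overlap = a, size = length(g))
    }, numeric(3L))
    pAdj <- p.adjust(res["p", ], method = "BH")
    ok <- which(pAdj < alpha)
    if (length(ok) == 0L) break
    best <- ok[order(pAdj[ok], res["p", ok], names(terms)[ok])][1L]
    out[[length(out) + 1L]] <- data.frame(
      term = names(terms)[best],
      overlap = unname(res["overlap", best]),
      querySize = length(query),
      termSize = unname(res["size", best]),
      backgroundSize = length(bg),
      pRaw = unname(res["p", best]),
      pAdjusted = unname(pAdj[best]))
    removed <- intersect(terms[[best]], bg)
    query <- setdiff(query, removed)
    bg <- setdiff(bg, removed)
    terms <- terms[-best]
  }
  if (length(out) == 0L)
    return(data.frame(term = character(), overlap = integer(),
                      querySize = integer(), termSize = integer(),
                      backgroundSize = integer(), pRaw = numeric(),
                      pAdjusted = numeric()))
  do.call(rbind, out)
}
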