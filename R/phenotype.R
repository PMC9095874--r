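#' Beta-cell proliferation index
#'
#' Ratio of the percentage of BrdU-positive, insulin-positive beta cells
#' cultured in 15 mmol/L glucose to the same percentage in 5 mmol/L glucose.
#' A zero denominator gives `NA` with a warning.
#'
#' @param pct15mM,pct5mM percentages in \[0, 100\] (vectorised).
#' @return proliferation index value(s).
#' @export
proliferationIndex <- function(pct15mM, pct5mM) {
  if (any(pct15mM < 0 | pct15mM > 100 | pct5mM < 0 | pct5mM > 100,
          na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  zero <- !is.na(pct5mM) & pct5mM == 0
  if (any(zero))
    warning(sum(zero), " value(s) with 0% at 5 mmol/L set to NA")
  out <- pct15mM / pct5mM
  out[zero] <- NA_real_
  out
}

#' Quartile association between circ/lin ratio and a phenotype
#'
#' Bins donors into quartiles of the circular/linear expression ratio and
#' tests for a monotone relationship with the phenotype: Spearman rank
#' correlation of ratio vs phenotype (exact p where ties permit) plus a
#' two-sided rank test of the first against the fourth quartile. Binning is
#' rank-based (stable order for tied ratios), so bin sizes differ by at most
#' one donor.
#'
#' @param ratio per-donor circular/linear ratio.
#' @param phenotype per-donor phenotype value (same length; incomplete
#'   donors are dropped listwise).
#' @param nBins number of bins (default 4).
#' @return list: `bins` (integer bin per retained donor), `summary`
#'   (data.frame of per-bin n and median phenotype), `spearmanRho`,
#'   `spearmanP`, `q1q4P`, `n`.
#' @export
quartileAssociation <- function(ratio, phenotype, nBins = 4L) {
  keep <- complete.cases(ratio, phenotype)
  r <- ratio[keep]; ph <- phenotype[keep]
  n <- length(r)
  if (n < 8L) stop("at least 8 complete donors required")
  if (length(unique(r)) == 1L) stop("all ratios tied; quartiles undefined")
  rk <- rank(r, ties.method = "first")
  bins <- as.integer(ceiling(nBins * rk / n))
  summary <- data.frame(
    bin = seq_len(nBins),
    n = as.integer(tabulate(bins, nBins)),
    median_phenotype = vapply(seq_len(nBins), function(b)
      median(ph[bins == b]), numeric(1L)))
  ct <- suppressWarnings(cor.test(r, ph, method = "spearman"))
  q14 <- suppressWarnings(wilcox.test(ph[bins == 1L], ph[bins == nBins]))
  list(bins = bins, summary = summary,
       spearmanRho = unname(ct$estimate), spearmanP = ct$p.value,
       q1q4P = q14$p.value, n = n)
}

#' Additive genotype-trait association with BH correction
#'
#' Per-SNP ordinary least squares of the trait on the allele-dosage coding
#' (0/1/2 copies of the coded allele), with listwise deletion of missing
#' genotypes per SNP and Benjamini-Hochberg adjustment across the tested
#' SNPs. Monomorphic SNPs are reported untestable. A trait with zero
#' variance in the analysis set yields beta 0 and p 1 (nothing to explain).
#'
#' @param donors data.frame with one dosage column per SNP and the trait
#'   column.
#' @param snps character vector of dosage column names to test.
#' @param trait name of the trait column.
#' @return data.frame: `snp`, `n`, `beta`, `se`, `raw_p`, `adjusted_p`,
#'   `testable`.
#' @export
genotypeAssociation <- function(donors, snps, trait) {
  miss <- setdiff(c(snps, trait), names(donors))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(snps, function(s) {
    keep <- complete.cases(donors[[s]], donors[[trait]])
    g <- donors[[s]][keep]; y <- donors[[trait]][keep]
    n <- length(g)
    if (n < 3L || length(unique(g)) < 2L)
      return(data.frame(snp = s, n = n, beta = NA_real_, se = NA_real_,
                        raw_p = NA_real_, testable = FALSE))
    if (stats::var(y) == 0)
      return(data.frame(snp = s, n = n, beta = 0, se = 0, raw_p = 1,
                        testable = TRUE))
    fit <- summary(lm(y ~ g))$coefficients
    data.frame(snp = s, n = n, beta = fit["g", "Estimate"],
               se = fit["g", "Std. Error"], raw_p = fit["g", "Pr(>|t|)"],
               testable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  ok <- out$testable
  out$adjusted_p[ok] <- p.adjust(out$raw_p[ok], method = "BH")
  rownames(out) <- NULL
  out[, c("snp", "n", "beta", "se", "raw_p", "adjusted_p", "testable")]
}
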