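test_that("jpm is reads per million mapped and conserves totals", {
  expect_equal(jpm(0, 1e6), 0)
  expect_equal(jpm(50, 1e7), 5)
  expect_error(jpm(5, 0), "positive")

  x <- fxBsj()
  counts <- assay(x, "counts")
  mapped <- colData(x)$mapped_reads
  jpmMat <- sweep(counts, 2, mapped, function(r, m) jpm(r, m))
  # conservation identity: sum over junctions of JPM * mapped / 1e6 = reads
  expect_equal(unname(colSums(jpmMat) * mapped / 1e6),
               unname(colSums(counts)))
})

test_that("circ/linear ratios handle zeros and flag unexpressed genes", {
  j <- c(g1 = 2, g2 = 0, g3 = 4)
  t <- c(g1 = 4, g2 = 10, g3 = 0)
  r <- circLinearRatio(j, t)
  expect_equal(r$ratio, c(0.5, 0, Inf))
  expect_true(r$flagged[3])
  expect_equal(r$expressed[1:2], c(FALSE, TRUE))
  expect_error(circLinearRatio(c(a = 1), c(b = 1)), "shared")
})

test_that("genome-wide log TPM and circ/lin ratio are negatively rank-correlated", {
  gw <- simulateGenomeWide(syntheticSpec())
  r <- circLinearRatio(setNames(gw$jpm, gw$gene), setNames(gw$tpm, gw$gene))
  rho <- cor(log(r$tpm), log(r$ratio), method = "spearman")
  expect_lt(rho, -0.5)
  expect_gt(rho, -0.7)
})

test_that("qPCR expression follows the -(dCt) convention", {
  expect_equal(qpcrExpression(25, c(20, 20)), -5)
  expect_equal(qpcrExpression(20, c(18, 22)), 0)
  # one template doubling (Ct - 1) adds one log2 unit
  expect_equal(qpcrExpression(24, c(20, 20)) - qpcrExpression(25, c(20, 20)), 1)
  expect_error(qpcrExpression(25, numeric()), "empty")
  expect_error(qpcrExpression(NaN, 20), "finite")
})

test_that("RNase R retention separates circular from linear assays", {
  expect_equal(rnaseRDepletion(3, 3), 1)
  expect_equal(rnaseRDepletion(0.1, 1), 0.1)
  expect_equal(rnaseRDepletion(-2, -2, log2Input = TRUE), 1)
  expect_error(rnaseRDepletion(1, 0), "zero")

  qp <- simulateRnaseRQpcr(syntheticSpec())
  ret <- rnaseRDepletion(qp$expr_treated, qp$expr_untreated, log2Input = TRUE)
  expect_equal(ret, qp$retention_true)
  gt <- groupTest(ret[qp$class == "circular"], ret[qp$class == "linear"],
                  "mann_whitney")
  expect_lt(gt$p, 0.05)
  expect_gt(mean(ret[qp$class == "circular"]),
            5 * mean(ret[qp$class == "linear"]))
})

test_that("compartment ratios recover the planted tenfold cytoplasmic excess", {
  expect_equal(compartmentRatio(5, 5, log2Input = FALSE), 1)
  expect_equal(compartmentRatio(-1, -4.32), 2^3.32, tolerance = 1e-6)

  fr <- simulateFractionationQpcr(syntheticSpec())
  agg <- stats::aggregate(cbind(expr_cytoplasmic, expr_nuclear) ~ assay + class,
                          fr, mean)
  ratios <- compartmentRatio(setNames(agg$expr_cytoplasmic, agg$assay),
                             setNames(agg$expr_nuclear, agg$assay))
  circ <- ratios[agg$class == "circular"]
  expect_true(all(circ > 5 & circ < 20))
  expect_warning(
    compartmentRatio(c(a = 1, b = 2), c(a = 0)), "skipped")
})

test_that("correlation matrices are symmetric, unit-diagonal and rank-invariant", {
  set.seed(11)
  x <- rnorm(30)
  m <- cbind(a = x, b = 2 * x + rnorm(30, 0, 1e-9), c = exp(x), d = rnorm(30))
  cp <- correlationMatrix(m, "pearson")
  cs <- correlationMatrix(m, "spearman")
  expect_lt(max(abs(cp - t(cp))), 1e-12)
  expect_equal(unname(diag(cp)), rep(1, 4))
  expect_equal(cp["a", "b"], 1, tolerance = 1e-6)
  expect_equal(cs["a", "c"], 1)             # rank-invariance of Spearman
  expect_lt(cp["a", "c"], 1)
  # constant feature gives NA with warning, never a silent 0
  expect_warning(cc <- correlationMatrix(cbind(k = rep(1, 30), x = x)),
                 "constant")
  expect_true(is.na(cc["k", "x"]))
})

test_that("synthetic cohort: circular assays exceed linear and correlate as planted", {
  d <- fxCohort()
  circCols <- c("circ_7_5", "circ_10_5", "circ_16_4", "circ_16_5", "circ_5_6")
  for (cc in circCols) {
    gt <- groupTest(d[[cc]], d$lin_1_2, "t")
    expect_lt(gt$p, 1e-8)
    expect_gt(mean(d[[cc]]), mean(d$lin_1_2))
  }
  cm <- correlationMatrix(d[, c(circCols, "lin_1_2")], "pearson")
  circCirc <- cm[circCols, circCols][upper.tri(diag(5))]
  circLin <- cm[circCols, "lin_1_2"]
  expect_true(all(circCirc > 0.8))
  expect_gt(mean(circCirc), mean(circLin))
})

test_that("exact Mann-Whitney p matches full rank enumeration", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  gt <- groupTest(a, b, "mann_whitney")
  # enumeration oracle over all C(6,3) = 20 labelings of the pooled ranks
  pool <- c(a, b)
  combos <- utils::combn(6, 3)
  stats <- apply(combos, 2, function(ix) sum(rank(pool)[ix]))
  obs <- sum(rank(pool)[1:3])
  pEnum <- min(1, 2 * min(mean(stats <= obs), mean(stats >= obs)))
  expect_equal(pEnum, 0.1)
  expect_equal(gt$p, pEnum)
})

test_that("group tests behave at the null and under strong shifts", {
  gt <- groupTest(c(1, 2, 3, 4), c(1, 2, 3, 4), "mann_whitney")
  expect_gt(gt$p, 0.9)
  expect_error(groupTest(rep(1, 3), rep(1, 3), "t"), "mann_whitney")
  # 3-SD shift at n = 20/20: power above 0.95 at alpha = 0.05
  set.seed(42)
  hits <- mean(replicate(200, {
    groupTest(rnorm(20), rnorm(20, 3), "mann_whitney")$p < 0.05
  }))
  expect_gt(hits, 0.95)
})

test_that("iterative enrichment accepts disjoint terms and matches the hypergeometric oracle", {
  bg <- paste0("g", 1:100)
  query <- paste0("g", 1:10)
  terms <- list(whole = query, half = paste0("g", c(1:5, 90:94)))
  res <- iterativeEnrichment(query, terms, bg)
  expect_equal(res$term[1], "whole")
  # fully-overlapping duplicate terms: only one accepted
  dup <- list(B = query, A = query)
  resDup <- iterativeEnrichment(query, dup, bg)
  expect_equal(nrow(resDup), 1L)
  expect_equal(resDup$term, "A")   # lexicographic tie-break

  # 2x2: 5/10 of query in term vs 10/100 of background
  term10 <- paste0("g", c(1:5, 60:64))
  res2 <- iterativeEnrichment(query, list(t = term10), bg)
  pOracle <- sum(stats::dhyper(5:10, 10, 90, 10))
  expect_equal(res2$pRaw, pOracle)

  expect_equal(nrow(iterativeEnrichment(query, list(), bg)), 0L)
  expect_error(iterativeEnrichment("zzz", terms, bg), "subset")
})
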