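test_that("median-of-ratios size factors match closed forms", {
  k <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  expect_equal(unname(computeSizeFactors(k)), c(1, 1))

  set.seed(1)
  a <- rpois(50, 100)
  k2 <- cbind(A = a, B = 2L * a)
  expect_equal(unname(computeSizeFactors(k2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  set.seed(2)
  k3 <- matrix(rpois(600, 50), ncol = 6)
  expect_lt(abs(mean(log(computeSizeFactors(k3)))), 1e-12)
})

test_that("size factors agree with DESeq2 up to geometric-mean centering", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  k <- matrix(rnbinom(2000, mu = 80, size = 10), ncol = 8)
  ours <- computeSizeFactors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("an all-zero sample is rejected by name", {
  k <- cbind(good = c(1, 2), bad = c(0, 0))
  expect_error(computeSizeFactors(k), "bad")
})

test_that("null features give zero fold change and p near 1", {
  k <- matrix(rep(c(5, 9, 12, 20, 50), 10), nrow = 5)
  rownames(k) <- paste0("g", 1:5)
  res <- nbWaldTest(k, condAB())
  expect_equal(res$log2FC, rep(0, 5))
  expect_true(all(res$pvalue > 0.99))
})

test_that("all-zero features get NA p-values excluded from BH", {
  set.seed(4)
  k <- nbCounts(50, 100, 0.05)
  k[7, ] <- 0L
  res <- nbWaldTest(k, condAB())
  expect_true(is.na(res$pvalue[7]))
  expect_true(is.na(res$padj[7]))
  # BH m excludes the NA feature
  expect_equal(res$padj[-7], bhAdjust(res$pvalue[-7]))
})

test_that("strong injected effects are recovered at stringent FDR", {
  set.seed(5)
  lfc <- rep(c(0, 2), c(900, 100))
  k <- nbCounts(1000, 100, 0.05, lfc = lfc)
  res <- nbWaldTest(k, condAB())
  hit <- res$padj < 0.01
  expect_gte(mean(hit[lfc == 2]), 0.95)
  expect_lte(sum(hit[lfc == 0]), 10)
  # fold changes estimated near truth
  expect_lt(abs(mean(res$log2FC[lfc == 2]) - 2), 0.15)
})

test_that("the Wald test is equivariant to per-sample scaling", {
  set.seed(6)
  k <- nbCounts(300, 100, 0.05, lfc = rep(c(0, 1.5), c(250, 50)))
  res1 <- nbWaldTest(k, condAB())
  k2 <- k
  k2[, 3] <- k2[, 3] * 4L
  res2 <- nbWaldTest(k2, condAB())
  expect_lt(max(abs(res1$log2FC - res2$log2FC)), 0.05)
})

test_that("fold changes agree with DESeq2 on strong signals", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  lfc <- rep(c(0, 2, -2), c(200, 50, 50))
  k <- nbCounts(300, 150, 0.05, lfc = lfc)
  ours <- nbWaldTest(k, condAB())
  dds <- DESeq2::DESeqDataSetFromMatrix(
    k, S4Vectors::DataFrame(condition = factor(condAB(), c("A", "B"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  strong <- lfc != 0
  expect_lt(mean(abs(ours$log2FC[strong] - ref$log2FoldChange[strong])),
            0.15)
  # significance calls concordant on strong effects
  expect_gt(mean((ours$padj < 0.01)[strong] == (ref$padj < 0.01)[strong]),
            0.95)
})

test_that("BH adjustment matches closed forms and handles edge cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.04, NA, 0.01)
  q <- bhAdjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bhAdjust(p[c(1, 3)]))
})

test_that("BH agrees elementwise with a hand-coded step-up oracle", {
  set.seed(8)
  for (i in 1:10) {
    p <- runif(100)
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("BH output is invariant to input order", {
  set.seed(9)
  p <- runif(200)
  perm <- sample(200)
  q <- bhAdjust(p)
  qPerm <- bhAdjust(p[perm])
  expect_equal(qPerm[order(perm)], q)
})

test_that("q-values are monotone in p-value rank", {
  set.seed(10)
  p <- runif(500)
  q <- bhAdjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("DE classification respects FDR, tiers and nesting", {
  d <- data.frame(feature_id = c("a", "b", "c"),
                  log2FC = c(1.5, 3, 1.5),
                  padj = c(0.005, 0.005, 0.02))
  cl <- classifyDE(d, fdr = 0.01, fcTiers = c(2, 4))
  expect_true(cl$results$tier2[1])
  expect_false(cl$results$tier4[1])
  expect_true(cl$results$tier4[2])
  expect_identical(cl$results$call[3], "unchanged")  # fails the FDR
  expect_identical(unname(cl$tierCounts),
                   c(2L, 2L, 1L))

  set.seed(11)
  lfc <- sample(rep(c(0, 1, 2.5), c(600, 200, 200))) *
    sample(c(-1, 1), 1000, replace = TRUE)
  k <- nbCounts(1000, 100, 0.05, lfc = lfc)
  res <- nbWaldTest(k, condAB())
  cl <- classifyDE(res, fdr = 0.01, fcTiers = c(2, 4))
  r <- cl$results
  expect_true(all(r$tier4 <= r$tier2))   # tiers nest
  big <- abs(lfc) == 2.5
  expect_gte(mean(r$tier4[big]), 0.9)    # tier-4 captures the 2.5 group
  expect_lte(sum(r$tier4[abs(lfc) == 1]), 2)  # and only that group
})

test_that("EISA leaves balanced genes unflagged and errors on mismatches", {
  set.seed(12)
  lfc <- rep(c(0, 2), c(80, 20))
  ex <- nbCounts(100, 200, 0.03, lfc = lfc)
  it <- nbCounts(100, 50, 0.03, lfc = lfc)   # same shift in introns
  res <- runEisa(ex, it, condAB())
  # no systematic exon-intron divergence, only sampling noise
  expect_lt(abs(mean(res$results$deltaDiff)), 0.1)
  expect_lt(mean(abs(res$results$deltaDiff)), 0.3)
  expect_lte(sum(res$results$postTxn), 2)

  it2 <- it[c(2:100, 1), ]
  rownames(it2)[100] <- "other"
  expect_error(runEisa(ex, it2, condAB()), "other")
})

test_that("EISA flags exon-only changes and reports the correlation", {
  set.seed(13)
  exLfc <- rep(c(0, 2), c(80, 20))
  ex <- nbCounts(100, 200, 0.05, lfc = exLfc)
  it <- nbCounts(100, 50, 0.05, lfc = 0)
  res <- runEisa(ex, it, condAB())
  flagged <- res$results$postTxn
  expect_gte(mean(flagged[exLfc == 2]), 0.9)
  expect_lte(sum(flagged[exLfc == 0]), 5)
  expect_true(all(res$results$padj[res$results$postTxn] < 0.05))
})

test_that("the expression floor removes weak genes before testing", {
  set.seed(14)
  ex <- nbCounts(50, 100, 0.05)
  it <- nbCounts(50, 2, 0.05)      # introns far below the floor
  res <- runEisa(ex, it, condAB(), floor = 8)
  expect_gt(res$nFiltered, 40)
})
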