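# direct ContactSet builder for statistical tests: n contacts at given
# per-sample expected counts, 5 vs 5
directContacts <- function(mu, phi = 0.05, lfc = 0, seed = 1,
                           nPer = 5L) {
  set.seed(seed)
  n <- length(mu)
  muMat <- cbind(matrix(rep(mu, nPer), ncol = nPer),
                 matrix(rep(mu * 2^lfc, nPer), ncol = nPer))
  k <- matrix(rnbinom(n * 2 * nPer, mu = muMat, size = 1 / phi),
              n, 2L * nPer)
  contactSet(k, bait = sprintf("b%04d", seq_len(n)),
             otherEnd = sprintf("o%04d", seq_len(n)),
             distance = exp(runif(n, log(1e4), log(1e6))),
             condition = rep(c("A", "B"), each = nPer))
}

test_that("ContactSet validity catches malformed objects", {
  expect_error(contactSet(matrix(1:4, 2), c("f1", "f2"), c("f1", "f3"),
                          c(100, 200), rep(c("A", "B"), each = 1)),
               "must differ")
  expect_error(contactSet(matrix(c(-1L, 1L, 1L, 1L), 2),
                          c("f1", "f2"), c("f3", "f4"),
                          c(100, 200), c("A", "B")),
               "nonnegative")
})

test_that("background fit recovers decay, biases and dispersion", {
  cfg <- simConfig(nGenes = 600, linkEnrichment = 1, biasSd = 0,
                   alteredContactFraction = 0, seed = 31)
  sim <- simulateDataset(cfg)
  bg <- fitContactBackground(sim$contacts)
  expect_lt(abs(bg$alpha - 1), 0.1)
  # all simulated biases equal -> estimates near 1
  expect_lt(max(abs(bg$baitBias - 1)), 0.35)
  expect_lt(abs(median(bg$baitBias) - 1), 0.1)
  expect_lt(abs(median(bg$oeBias) - 1), 0.1)
  expect_lt(abs(bg$dispersion - 0.05), 0.03)
})

test_that("doubling all counts leaves the decay exponent unchanged", {
  cfg <- simConfig(nGenes = 500, linkEnrichment = 1, biasSd = 0,
                   alteredContactFraction = 0, seed = 32)
  sim <- simulateDataset(cfg)
  bg1 <- fitContactBackground(sim$contacts)
  rd <- rowData(sim$contacts)
  doubled <- contactSet(2L * assay(sim$contacts), rd$bait_frag_id,
                        rd$otherend_frag_id, rd$distance,
                        as.character(colData(sim$contacts)$condition),
                        colData(sim$contacts)$replicate)
  bg2 <- fitContactBackground(doubled)
  expect_lt(abs(bg1$alpha - bg2$alpha), 0.02)
  expect_gt(bg2$intercept, bg1$intercept)   # scale moves to the intercept
})

test_that("fit preconditions are enforced", {
  cs <- directContacts(rep(50, 100))
  expect_error(fitContactBackground(cs), "at least 500")
  csNarrow <- contactSet(matrix(rpois(600 * 2, 20), 600),
                         sprintf("b%03d", 1:600), sprintf("o%03d", 1:600),
                         runif(600, 1e5, 1.5e5), c("A", "B"))
  expect_error(fitContactBackground(csNarrow), "decade")
})

test_that("scores are near zero at expectation and monotone in counts", {
  cs <- directContacts(rep(20, 1000), seed = 33)
  bg <- fitContactBackground(cs, trimRatio = 1e6)  # nothing to trim here
  sc <- scoreContacts(cs, bg)
  expect_lt(quantile(sc$score, 0.95), 5)
  expect_true(all(!sc$valid[sc$score <= 5]))

  # monotonicity: same expected value, increasing observed count
  one <- cs[1, ]
  exp1 <- bg$expected[rowData(one)$contact_id] * 5
  phi <- bg$dispersion
  obs <- seq(0, 200, by = 10)
  mu1 <- bg$expected[rowData(one)$contact_id]
  varSum <- exp1 + phi * mu1^2 * 5
  p <- pnbinom(obs - 1, mu = exp1, size = exp1^2 / (varSum - exp1),
               lower.tail = FALSE)
  expect_true(all(diff(-log10(p)) >= 0))
})

test_that("strongly enriched contacts are called valid", {
  hits <- 0L
  for (seed in 1:20) {
    mu <- rep(2, 600)
    mu[1] <- 20          # expected 20 where background predicts 2
    cs <- directContacts(mu, seed = 40 + seed)
    # background from the null part of the table
    bg <- fitContactBackground(cs)
    sc <- scoreContacts(cs, bg)
    id1 <- rowData(cs)$contact_id[1]
    hits <- hits + any(sc$valid[sc$contact_id == id1])
  }
  expect_gte(hits / 20, 0.95)
})

test_that("scoring demands a matching background domain", {
  cs <- directContacts(rep(20, 600), seed = 60)
  bg <- fitContactBackground(cs)
  extra <- contactSet(matrix(10L, 2, 10), c("x1", "x2"), c("y1", "y2"),
                      c(5e4, 6e4), condAB(),
                      contactId = c("other1", "other2"))
  expect_error(scoreContacts(extra, bg), "absent from background")
})

test_that("differential contacts respect the mean-count prefilter", {
  # one contact with mean 8 in condition A must be excluded by construction
  set.seed(62)
  k <- rbind(matrix(rnbinom(99 * 10, mu = 50, size = 20), 99),
             c(rpois(5, 8), rpois(5, 50)))
  cs <- contactSet(k, sprintf("b%03d", 1:100), sprintf("o%03d", 1:100),
                   runif(100, 1e4, 1e6), condAB())
  res <- differentialContacts(cs, minMean = 10)
  lastId <- rowData(cs)$contact_id[100]
  expect_false(lastId %in% res$results$feature_id)
  expect_gte(res$nFiltered, 1L)

  # equal-count contacts stay unchanged
  expect_lte(length(res$alteredIds), 5)
})

test_that("differential contact calls agree with edgeR on strong effects", {
  skip_if_not_installed("edgeR")
  set.seed(64)
  lfc <- rep(c(0, 1.5), c(270, 30)) * sample(c(-1, 1), 300, replace = TRUE)
  cs <- directContacts(rep(60, 300), lfc = lfc, seed = 64)
  ours <- differentialContacts(cs, fdr = 0.1)
  k <- assay(cs)
  y <- edgeR::DGEList(k, group = factor(condAB(), c("A", "B")))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, model.matrix(~condAB()))
  et <- edgeR::exactTest(y)
  refQ <- p.adjust(et$table$PValue, "BH")
  refAltered <- rowData(cs)$contact_id[refQ < 0.1]
  strong <- rowData(cs)$contact_id[lfc != 0]
  # both routes recover essentially all injected contacts
  expect_gte(mean(strong %in% ours$alteredIds), 0.9)
  expect_gte(mean(strong %in% refAltered), 0.9)
  # and the two altered sets agree closely overall
  agree <- length(intersect(ours$alteredIds, refAltered)) /
    length(union(ours$alteredIds, refAltered))
  expect_gte(agree, 0.8)
})

test_that("injected 2-fold contacts are detected at FDR 0.1", {
  set.seed(63)
  lfc <- rep(c(0, 1), c(450, 50))
  cs <- directContacts(rep(50, 500), lfc = lfc, seed = 63)
  res <- differentialContacts(cs)
  ids <- rowData(cs)$contact_id
  called <- ids %in% res$alteredIds
  expect_gte(mean(called[lfc == 1]), 0.8)
  expect_lte(sum(called[lfc == 0]), 10)
  # the >2-fold subset is the |log2FC| > 1 part of the altered set
  expect_true(all(res$fold2Ids %in% res$alteredIds))
})
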