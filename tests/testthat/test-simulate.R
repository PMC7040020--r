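cfgSmall <- simConfig(nGenes = 120, seed = 9)

test_that("simConfig validates its parameters", {
  expect_error(simConfig(deFraction = 1.5), "\\[0, 1\\]")
  expect_error(simConfig(decayExponent = 0), "> 0")
  expect_error(simConfig(samplesPerCondition = 1), "2 samples")
  expect_silent(validObject(simConfig()))
})

test_that("identical configs give bit-identical datasets", {
  s1 <- simulateDataset(cfgSmall)
  s2 <- simulateDataset(simConfig(nGenes = 120, seed = 9))
  expect_identical(assay(s1$rna$exon), assay(s2$rna$exon))
  expect_identical(assay(s1$contacts), assay(s2$contacts))
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(truthTable(s1$truth, "genes"),
                   truthTable(s2$truth, "genes"))
})

test_that("counts are nonnegative integers and truth labels are consistent", {
  sim <- simulateDataset(cfgSmall)
  for (m in list(assay(sim$rna$exon), assay(sim$rna$intron),
                 assay(sim$chip$H3K27Ac$counts), assay(sim$contacts))) {
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
  }
  gt <- truthTable(sim$truth, "genes")
  expect_false(any(gt$deDirection != 0 & gt$postTxn))  # label partition
  rt <- truthTable(sim$truth, "regions")
  expect_true(all(rt$region_id %in% c(
    names(sim$sequences),
    unlist(lapply(sim$chip, function(a) mcols(a$regions)$region_id)))))
  ct <- truthTable(sim$truth, "contacts")
  expect_true(all(ct$contact_id %in% rowData(sim$contacts)$contact_id))
})

test_that("null expression config centres empirical fold changes at zero", {
  gm <- buildGenome(2, 2000, 4000, seed = 5)
  cfg <- simConfig(nGenes = 2000, deFraction = 0, postTxnFraction = 0,
                   seed = 5)
  rna <- simulateRnaseq(gm, cfg)
  k <- assay(rna$exon)
  cond <- rna$samples$condition
  sf <- computeSizeFactors(k)
  q <- sweep(k, 2, sf, "/")
  lfc <- log2(rowMeans(q[, cond == "leiomyoma"]) + 0.5) -
    log2(rowMeans(q[, cond == "myometrium"]) + 0.5)
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("DE set size is binomially plausible", {
  gm <- buildGenome(2, 1000, 4000, seed = 6)
  cfg <- simConfig(nGenes = 1000, deFraction = 0.2, seed = 6)
  rna <- simulateRnaseq(gm, cfg)
  nDe <- sum(truthTable(rna$truth, "genes")$deDirection != 0)
  expect_lt(abs(nDe - 200), 3 * sqrt(1000 * 0.2 * 0.8))
})

test_that("post-transcriptional genes change exonic means only", {
  sim <- simulateDataset(simConfig(nGenes = 400, postTxnFraction = 0.15,
                                   rnaDispersionRange = c(0.01, 0.02),
                                   seed = 13))
  gt <- truthTable(sim$truth, "genes")
  pt <- gt$gene_id[gt$postTxn]
  cond <- sim$samples$condition
  qI <- sweep(assay(sim$rna$intron), 2, sim$samples$sizeFactor, "/")
  qE <- sweep(assay(sim$rna$exon), 2, sim$samples$sizeFactor, "/")
  dI <- log2(rowMeans(qI[pt, cond == "leiomyoma"]) + 0.5) -
    log2(rowMeans(qI[pt, cond == "myometrium"]) + 0.5)
  dE <- log2(rowMeans(qE[pt, cond == "leiomyoma"]) + 0.5) -
    log2(rowMeans(qE[pt, cond == "myometrium"]) + 0.5)
  # intronic means equal by construction -> only sampling noise remains
  expect_lt(mean(abs(dI)), 0.25)
  expect_gt(mean(abs(dE)), 1)
})

test_that("usage genes carry one up- and one down-enhancer", {
  sim <- simulateDataset(cfgSmall)
  lt <- truthTable(sim$truth, "links")
  rt <- truthTable(sim$truth, "regions")
  lfc <- setNames(rt$log2FC, rt$region_id)
  gt <- truthTable(sim$truth, "genes")
  for (g in gt$gene_id[gt$usage]) {
    roles <- lt[lt$gene_id == g & lt$usageRole != "none", ]
    expect_setequal(roles$usageRole, c("up", "down"))
    expect_gt(lfc[roles$region_id[roles$usageRole == "up"]], 0)
    expect_lt(lfc[roles$region_id[roles$usageRole == "down"]], 0)
  }
})

test_that("unknown assay names are rejected", {
  gm <- buildGenome(1, 10, 4000, seed = 2)
  rna <- simulateRnaseq(gm, simConfig(nGenes = 10, seed = 2))
  expect_error(simulateChip(gm, simConfig(nGenes = 10, seed = 2),
                            rna$truth, assays = c("H3K27Ac", "NOPE")),
               "unknown assay")
})

test_that("injected coupling between TF and acetylation changes is recovered", {
  for (rho in c(0, 0.8)) {
    sim <- simulateDataset(simConfig(nGenes = 900, tfCoupling = rho,
                                     seed = 21))
    rt <- truthTable(sim$truth, "regions")
    tf <- rt[rt$assay == "FOS", ]
    acet <- setNames(rt$log2FC[rt$assay == "H3K27Ac"],
                     rt$region_id[rt$assay == "H3K27Ac"])
    expect_gt(nrow(tf), 2000)
    r <- cor(tf$log2FC, acet[tf$k27_region_id])
    expect_lt(abs(r - rho), 0.1)
  }
})

test_that("contact counts follow the configured distance decay", {
  cfg <- simConfig(nGenes = 800, linkEnrichment = 1, biasSd = 0,
                   alteredContactFraction = 0, decayExponent = 1,
                   seed = 17)
  sim <- simulateDataset(cfg)
  m <- rowMeans(assay(sim$contacts))
  d <- contactDistance(sim$contacts)
  keep <- m > 0.5
  slope <- unname(coef(lm(log(m[keep]) ~ log(d[keep])))[2])
  expect_lt(abs(slope + 1), 0.1)

  # power law: doubling the distance halves the expected count at alpha=1
  ct <- truthTable(sim$truth, "contacts")
  fit <- lm(log(ct$expected) ~ log(d))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-6)
})

test_that("zero alteration fraction yields no altered contacts", {
  sim <- simulateDataset(simConfig(nGenes = 100,
                                   alteredContactFraction = 0, seed = 3))
  expect_identical(sum(truthTable(sim$truth, "contacts")$altered), 0L)
})

test_that("every designed link has a contact and lands in its fragment", {
  sim <- simulateDataset(cfgSmall)
  lt <- truthTable(sim$truth, "links")
  expect_true(all(!is.na(lt$contact_id)))
  rd <- as.data.frame(rowData(sim$contacts))
  idx <- match(lt$contact_id, rd$contact_id)
  expect_identical(rd$bait_frag_id[idx], lt$bait_frag_id)
  expect_identical(rd$otherend_frag_id[idx], lt$enhancer_frag_id)
})

test_that("planted motif occurrences track the differential labels", {
  sim <- simulateDataset(cfgSmall)
  rt <- truthTable(sim$truth, "regions")
  rt <- rt[rt$assay == "H3K27Ac", ]
  hasMotif <- vapply(sim$sequences, function(s)
    grepl("TGACTCA", s, fixed = TRUE) ||
      grepl("TGAGTCA", s, fixed = TRUE), logical(1))
  dr <- rt$region_id[rt$differential]
  nr <- rt$region_id[!rt$differential]
  expect_gt(mean(hasMotif[dr]), 0.6)
  expect_lt(mean(hasMotif[nr]), 0.2)
})
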