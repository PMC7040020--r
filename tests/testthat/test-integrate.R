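test_that("fragment assignment handles containment and boundary spanning", {
  gm <- buildGenome(1, 5, 4000, seed = 44)
  fr <- fragments(gm)
  inside <- GRanges(seqnames(fr)[10],
                    IRanges(start(fr)[10] + 10L, start(fr)[10] + 50L))
  mcols(inside)$region_id <- "in"
  a <- assignToFragments(inside, gm)
  expect_identical(a$frag_id, mcols(fr)$frag_id[10])

  o <- order(start(fr[seqnames(fr) == as.character(seqnames(fr))[10]]))
  spanning <- GRanges(as.character(seqnames(fr))[10],
                      IRanges(end(fr)[10] - 20L, end(fr)[10] + 20L))
  mcols(spanning)$region_id <- "span"
  a2 <- assignToFragments(spanning, gm)
  expect_identical(sort(a2$frag_id),
                   sort(mcols(fr)$frag_id[c(10, 11)]))

  expect_error(assignToFragments(GRanges("chrZ", IRanges(1, 5)), gm),
               "unknown chromosome")
})

test_that("fragment assignment matches a brute-force oracle and covers", {
  set.seed(45)
  gm <- tinyGenome()
  regions <- randomRegions(gm, 5000, 50, 5000)
  ours <- assignToFragments(regions, gm)
  oracle <- assignOracle(regions, gm)
  key <- function(d) sort(paste(d$region_id, d$frag_id))
  expect_identical(key(ours), key(oracle))
  # covering map: per-region overlap lengths sum to the region width
  tot <- tapply(ours$overlap, ours$region_id, sum)
  expect_equal(as.vector(tot[mcols(regions)$region_id]),
               as.vector(width(regions)))
})

# hand-built micro-world for the linking logic: 2 genes, 3 enhancer
# fragments, noise-free counts equal to their expectations
microLink <- function() {
  scores <- data.frame(
    contact_id = rep(c("c1", "c2", "c3", "c4"), 2),
    condition = rep(c("A", "B"), each = 4),
    score = c(20, 9, 0.2, 30, 18, 0.4, 7, 28),
    stringsAsFactors = FALSE)
  scores$valid <- scores$score > 5
  cs <- contactSet(matrix(10L, 4, 4),
                   bait = c("bf1", "bf1", "bf2", "bf2"),
                   otherEnd = c("ef1", "ef2", "ef3", "ef1"),
                   distance = c(5e4, 6e4, 7e4, 8e4),
                   condition = rep(c("A", "B"), each = 2),
                   contactId = c("c1", "c2", "c3", "c4"))
  assign <- data.frame(
    region_id = c("r1", "r2", "r3"),
    frag_id = c("ef1", "ef2", "ef3"), overlap = 100L,
    stringsAsFactors = FALSE)
  baits <- data.frame(gene_id = c("g1", "g2"),
                      bait_frag_id = c("bf1", "bf2"),
                      stringsAsFactors = FALSE)
  list(cs = cs, scores = scores, assign = assign, baits = baits)
}

test_that("links require a valid contact and an assigned enhancer", {
  mw <- microLink()
  links <- linkEnhancersToGenes(mw$cs, mw$scores, mw$assign, mw$baits)
  # c3 only becomes valid in condition B; all four contacts link
  expect_setequal(paste(links$gene_id, links$enhancer_frag_id),
                  c("g1 ef1", "g1 ef2", "g2 ef3", "g2 ef1"))
  expect_true(all(links$valid_ref | links$valid_alt))

  none <- mw$scores
  none$valid <- FALSE
  expect_identical(nrow(linkEnhancersToGenes(mw$cs, none, mw$assign,
                                             mw$baits)), 0L)

  # a bait serving two genes links them both
  baits2 <- rbind(mw$baits,
                  data.frame(gene_id = "g3", bait_frag_id = "bf1"))
  links2 <- linkEnhancersToGenes(mw$cs, mw$scores, mw$assign, baits2)
  expect_setequal(links2$gene_id[links2$enhancer_frag_id == "ef2"],
                  c("g1", "g3"))
})

test_that("CRE classes follow the status table exhaustively", {
  mw <- microLink()
  links <- linkEnhancersToGenes(mw$cs, mw$scores, mw$assign, mw$baits)
  acet <- data.frame(feature_id = c("r1", "r2", "r3"),
                     log2FC = c(2, -1.8, 0.1),
                     padj = c(0.001, 0.001, 0.8),
                     call = c("up", "down", "unchanged"),
                     stringsAsFactors = FALSE)
  cd <- list(alteredIds = c("c2", "c3"))
  cres <- classifyCREs(links, acet, cd, mw$assign)
  cls <- setNames(cres$cre_class, cres$enhancer_frag_id)
  expect_identical(unname(cls["ef1"]), "i")    # stable + differential
  expect_identical(unname(cls["ef2"]), "iii")  # altered + differential
  expect_identical(unname(cls["ef3"]), "ii")   # altered + unchanged
  # the remaining combination
  cres2 <- classifyCREs(links, transform(acet, call = "unchanged"),
                        list(alteredIds = character()), mw$assign)
  expect_true(all(cres2$cre_class == "unmodified"))
  # classes partition the linked fragments
  expect_identical(sum(table(cres$cre_class)),
                   length(unique(links$enhancer_frag_id)))
  # missing diff entry is an error naming the fragment
  expect_error(classifyCREs(links, acet[1:2, ], cd,
                            mw$assign[1:2, ]), "ef3")
})

test_that("usage events need opposite-sign differential enhancers", {
  mw <- microLink()
  links <- linkEnhancersToGenes(mw$cs, mw$scores, mw$assign, mw$baits)
  up2 <- data.frame(feature_id = c("r1", "r2", "r3"),
                    log2FC = c(2, 1.5, 0),
                    call = c("up", "up", "unchanged"),
                    stringsAsFactors = FALSE)
  expect_identical(
    detectDifferentialUsage(links, up2, mw$assign)$nGenes, 0L)

  mix <- transform(up2, log2FC = c(2, -1.5, 0),
                   call = c("up", "down", "unchanged"))
  ev <- detectDifferentialUsage(links, mix, mw$assign)
  expect_identical(ev$nGenes, 1L)
  expect_identical(ev$events[[1]]$gene_id, "g1")
  expect_setequal(c(ev$events[[1]]$up, ev$events[[1]]$down),
                  c("ef1", "ef2"))

  # swapping condition labels negates fold changes and swaps up/down
  neg <- transform(mix, log2FC = -log2FC,
                   call = c("down", "up", "unchanged"))
  ev2 <- detectDifferentialUsage(links, neg, mw$assign)
  expect_identical(ev2$events[[1]]$up, ev$events[[1]]$down)
  expect_identical(ev2$events[[1]]$down, ev$events[[1]]$up)
})

test_that("designed links are recovered on the default config", {
  out <- defaultPipelineRun()
  lt <- truthTable(out$sim$truth, "links")
  got <- unique(paste(out$links$gene_id, out$links$enhancer_frag_id))
  want <- unique(paste(lt$gene_id, lt$enhancer_frag_id))
  expect_gte(mean(want %in% got), 0.9)     # sensitivity
  expect_lte(mean(!(got %in% want)), 0.1)  # spurious links
})

test_that("TF integration recovers the coupling and counts consistently", {
  out <- defaultPipelineRun()
  expect_true(all(abs(out$tf$correlations - 0.8) < 0.15))
  # counting contract: every counted enhancer fragment links to a DE gene
  de <- out$de$results$feature_id[out$de$results$call != "unchanged"]
  tfNames <- names(out$tf$correlations)
  for (tf in tfNames) {
    n <- out$tf$diffTfEnhancersLinkedToDE[[tf]]
    linked <- unique(out$links$enhancer_frag_id[out$links$gene_id %in% de])
    expect_lte(n, length(linked))
  }
})

test_that("integrateTF reports near-zero correlation when uncoupled", {
  sim <- simulateDataset(simConfig(nGenes = 700, tfCoupling = 0, seed = 77))
  peaks <- lapply(sim$chip, function(a)
    differentialRegions(a$counts, reference = "myometrium"))
  gm <- sim$genome
  enhAssign <- assignToFragments(sim$chip$H3K27Ac$regions, gm)
  tfA <- list(FOS = assignToFragments(sim$chip$FOS$regions, gm))
  fake <- integrateTF(
    data.frame(gene_id = character(), enhancer_frag_id = character()),
    peaks$H3K27Ac$results, list(FOS = peaks$FOS$results), tfA,
    peaks$H3K27Ac$results[0, ], enhAssign)
  expect_lt(abs(fake$correlations[["FOS"]]), 0.1)
})
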