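# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

# small genome shared by interval tests
tinyGenome <- function(seed = 4L) buildGenome(
  nChrom = 1L, nGenes = 40L, meanFragmentLen = 1000, seed = seed)

# memoized default-config pipeline run (used by several end-to-end tests)
.pipeCache <- new.env(parent = emptyenv())
defaultPipelineRun <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(.pipeCache[[key]]))
    .pipeCache[[key]] <- runPipeline(pipelineConfig(seed = seed))
  .pipeCache[[key]]
}

# ---- independent oracles ------------------------------------------------

# naive Benjamini-Hochberg step-up, written from the definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (k in seq_len(m)) {
    q[k] <- min(1, min(sorted[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force interval merge + replicate support
consensusOracle <- function(sets, minSupport) {
  all <- do.call(rbind, lapply(sets, function(g)
    data.frame(chrom = as.character(seqnames(g)), start = start(g),
               end = end(g))))
  all <- all[order(all$chrom, all$start), ]
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(all))) {
    r <- all[i, ]
    # closed coordinates: abutting intervals (start == end + 1) merge too
    if (is.null(cur) || r$chrom != cur$chrom || r$start > cur$end + 1L) {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- r
    } else cur$end <- max(cur$end, r$end)
  }
  merged[[length(merged) + 1L]] <- cur
  md <- do.call(rbind, merged)
  support <- vapply(seq_len(nrow(md)), function(i) {
    sum(vapply(sets, function(g) any(
      as.character(seqnames(g)) == md$chrom[i] &
        start(g) <= md$end[i] & end(g) >= md$start[i]), logical(1)))
  }, integer(1))
  md$support <- support
  md[md$support >= minSupport, , drop = FALSE]
}

# per-region annotation oracle written from the window definitions
annotateOracle <- function(regions, genome, promWin = c(-1000L, 100L),
                           ttsWin = c(-100L, 1000L)) {
  genes <- geneRanges(genome)
  gid <- mcols(genes)$gene_id
  neg <- as.character(strand(genes)) == "-"
  tss <- ifelse(neg, end(genes), start(genes))
  tes <- ifelse(neg, start(genes), end(genes))
  ex <- exonRanges(genome); inr <- intronRanges(genome)
  mid <- (start(regions) + end(regions)) %/% 2L
  out <- character(length(regions))
  for (i in seq_along(regions)) {
    p <- mid[i]
    chrOk <- as.character(seqnames(genes)) ==
      as.character(seqnames(regions))[i]
    inWin <- function(anchor, win) {
      lo <- ifelse(neg, anchor - win[2], anchor + win[1])
      hi <- ifelse(neg, anchor - win[1], anchor + win[2])
      chrOk & p >= pmin(lo, hi) & p <= pmax(lo, hi)
    }
    if (any(inWin(tss, promWin))) out[i] <- "promoter"
    else if (any(inWin(tes, ttsWin))) out[i] <- "tts"
    else if (any(as.character(seqnames(ex)) ==
                   as.character(seqnames(regions))[i] &
                 start(ex) <= p & end(ex) >= p)) out[i] <- "exonic"
    else if (any(as.character(seqnames(inr)) ==
                   as.character(seqnames(regions))[i] &
                 start(inr) <= p & end(inr) >= p)) out[i] <- "intronic"
    else out[i] <- "intergenic"
  }
  out
}

# brute-force region -> fragment overlap oracle
assignOracle <- function(regions, genome) {
  fr <- fragments(genome)
  res <- list()
  for (i in seq_along(regions)) {
    hit <- as.character(seqnames(fr)) ==
      as.character(seqnames(regions))[i] &
      start(fr) <= end(regions)[i] & end(fr) >= start(regions)[i]
    if (any(hit))
      res[[i]] <- data.frame(
        region_id = mcols(regions)$region_id[i],
        frag_id = mcols(fr)$frag_id[hit], stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# brute-force PWM rescan on one strand via direct per-window scoring
scanOracle <- function(seqs, p) {
  lo <- p@logOdds
  L <- ncol(lo)
  hits <- list()
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  scoreAt <- function(s, i) {
    sum(vapply(seq_len(L), function(j) {
      b <- substr(s, i + j - 1L, i + j - 1L)
      if (b %in% c("A", "C", "G", "T")) lo[b, j] else 0
    }, numeric(1)))
  }
  for (id in names(seqs)) {
    s <- seqs[[id]]; w <- nchar(s)
    if (w < L) next
    for (i in seq_len(w - L + 1L)) {
      sc <- scoreAt(s, i)
      if (sc >= p@threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          region_id = id, position = i, strand = "+", score = sc)
    }
    sr <- rc(s)
    for (i in seq_len(w - L + 1L)) {
      sc <- scoreAt(sr, i)
      if (sc >= p@threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          region_id = id, position = w - L - i + 2L, strand = "-",
          score = sc)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(region_id = character(),
                                      position = integer(),
                                      strand = character(),
                                      score = numeric())
  out[order(out$region_id, out$position, out$strand), , drop = FALSE]
}

# random region set over a genome
randomRegions <- function(genome, n, minW = 50, maxW = 3000) {
  chrs <- names(genome@chromLengths)
  chrom <- sample(chrs, n, replace = TRUE)
  w <- as.integer(runif(n, minW, maxW))
  st <- as.integer(runif(n, 1, genome@chromLengths[chrom] - w - 1))
  gr <- GRanges(chrom, IRanges(st, width = w))
  mcols(gr)$region_id <- sprintf("r%05d", seq_len(n))
  names(gr) <- mcols(gr)$region_id
  gr
}

# NB count matrix helper for direct statistical tests
nbCounts <- function(n, mu, phi, nPer = 5L, lfc = 0, sf = NULL) {
  ns <- 2L * nPer
  mu <- rep_len(mu, n)
  lfc <- rep_len(lfc, n)
  if (is.null(sf)) sf <- rep(1, ns)
  muMat <- cbind(matrix(rep(mu, nPer), ncol = nPer),
                 matrix(rep(mu * 2^lfc, nPer), ncol = nPer))
  muMat <- sweep(muMat, 2, sf, "*")
  k <- matrix(rnbinom(n * ns, mu = muMat, size = 1 / phi), n, ns)
  rownames(k) <- sprintf("f%04d", seq_len(n))
  k
}

condAB <- function(nPer = 5L) rep(c("A", "B"), each = nPer)
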