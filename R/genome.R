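#' Build a toy genome with genes and a restriction-fragment partition
#'
#' Generates a deterministic toy genome: each chromosome is tiled exactly by
#' restriction fragments whose lengths follow a geometric-like distribution
#' around \code{meanFragmentLen} with a 200 bp minimum, emulating a 6-cutter
#' digest. Genes (alternating exon/intron structure, random strand) are
#' placed uniformly; the TSS is the strand-aware 5' end and, because the
#' fragments partition the chromosome, every TSS lies in exactly one
#' fragment.
#'
#' @param nChrom number of chromosomes.
#' @param nGenes total number of genes, spread across chromosomes.
#' @param meanFragmentLen mean restriction-fragment length in bp (>= 200).
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @return A \code{\linkS4class{GenomeModel}}.
#' @export
#' @examples
#' gm <- buildGenome(nChrom = 1, nGenes = 10, meanFragmentLen = 4000, seed = 7)
#' gm
buildGenome <- function(nChrom = 2L, nGenes = 1000L, meanFragmentLen = 4000,
                        seed = 1L) {
  if (nChrom < 1L || nGenes < 1L)
    stop("nChrom and nGenes must be positive")
  if (meanFragmentLen < 200)
    stop("meanFragmentLen must be >= 200")
  set.seed(subSeed(seed, "genome"))

  geneChrom <- sort(rep_len(seq_len(nChrom), nGenes))
  chromNames <- paste0("chr", seq_len(nChrom))

  # gene structures: nExons alternating exon/intron blocks
  nExons <- 2L + rpois(nGenes, 3L)
  geneList <- vector("list", nGenes)
  exonList <- vector("list", nGenes)
  intronList <- vector("list", nGenes)
  geneLen <- integer(nGenes)
  for (i in seq_len(nGenes)) {
    ne <- nExons[i]
    exLen <- pmax(100L, as.integer(rlogunif(ne, 150, 1500)))
    inLen <- pmax(200L, as.integer(rlogunif(ne - 1L, 500, 8000)))
    geneLen[i] <- sum(exLen) + sum(inLen)
    offs <- cumsum(c(0L, as.vector(rbind(exLen, c(inLen, 0L)))[
      seq_len(2L * ne - 1L)]))
    exStart <- offs[seq(1L, 2L * ne - 1L, by = 2L)]
    exonList[[i]] <- cbind(exStart, exStart + exLen - 1L)
    if (ne > 1L) {
      inStart <- offs[seq(2L, 2L * ne - 2L, by = 2L)]
      intronList[[i]] <- cbind(inStart, inStart + inLen - 1L)
    } else intronList[[i]] <- matrix(integer(), 0L, 2L)
  }

  # chromosome length: genes plus intergenic room, then fragment tiling
  chromLengths <- integer(nChrom)
  fragAll <- vector("list", nChrom)
  genesPerChrom <- tabulate(geneChrom, nChrom)
  minLen <- 2e6
  for (cc in seq_len(nChrom)) {
    need <- sum(geneLen[geneChrom == cc]) * 4 + 1e6
    L <- as.integer(max(minLen, need))
    # geometric-like fragment lengths, min 200
    p <- 1 / (meanFragmentLen - 199)
    lens <- integer(0)
    while (sum(lens) < L)
      lens <- c(lens, 200L + rgeom(ceiling(L / meanFragmentLen) + 50L, p))
    cum <- cumsum(lens)
    k <- which(cum >= L)[1]
    lens <- lens[seq_len(k)]
    lens[k] <- lens[k] - (cum[k] - L)  # trim last fragment to chromosome end
    if (lens[k] < 200L && k > 1L) {    # merge a too-short terminal fragment
      lens[k - 1L] <- lens[k - 1L] + lens[k]
      lens <- lens[seq_len(k - 1L)]
    }
    st <- cumsum(c(1L, lens[-length(lens)]))
    fragAll[[cc]] <- data.frame(chrom = chromNames[cc], start = st,
                                width = lens)
    chromLengths[cc] <- L
  }
  fragDf <- do.call(rbind, fragAll)
  frags <- GRanges(fragDf$chrom, IRanges(fragDf$start, width = fragDf$width))
  mcols(frags)$frag_id <- sprintf("frag%05d", seq_along(frags))
  names(frags) <- mcols(frags)$frag_id
  names(chromLengths) <- chromNames

  # place genes; each TSS gets a restriction fragment of its own, so a
  # promoter bait serves exactly one gene in the designed truth
  strandVec <- sample(c("+", "-"), nGenes, replace = TRUE)
  drawStarts <- function(idx) {
    L <- chromLengths[geneChrom[idx]]
    as.integer(runif(length(idx), 1, L - geneLen[idx] - 1))
  }
  geneStart <- drawStarts(seq_len(nGenes))
  for (pass in 1:10) {
    tssPos <- ifelse(strandVec == "-", geneStart + geneLen - 1L, geneStart)
    ovTss <- findOverlaps(
      GRanges(chromNames[geneChrom], IRanges(tssPos, width = 1L)),
      frags, select = "first")
    clash <- which(duplicated(ovTss))
    if (!length(clash)) break
    geneStart[clash] <- drawStarts(clash)
  }
  geneId <- sprintf("gene%04d", seq_len(nGenes))
  genes <- GRanges(chromNames[geneChrom],
                   IRanges(geneStart, width = geneLen), strand = strandVec)
  mcols(genes)$gene_id <- geneId
  names(genes) <- geneId

  exAbs <- do.call(rbind, lapply(seq_len(nGenes), function(i)
    cbind(i, geneStart[i] + exonList[[i]])))
  exons <- GRanges(chromNames[geneChrom[exAbs[, 1]]],
                   IRanges(exAbs[, 2], exAbs[, 3]),
                   strand = strandVec[exAbs[, 1]])
  mcols(exons)$gene_id <- geneId[exAbs[, 1]]
  inAbs <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
    m <- intronList[[i]]
    if (nrow(m) == 0L) return(NULL)
    cbind(i, geneStart[i] + m)
  }))
  introns <- GRanges(chromNames[geneChrom[inAbs[, 1]]],
                     IRanges(inAbs[, 2], inAbs[, 3]),
                     strand = strandVec[inAbs[, 1]])
  mcols(introns)$gene_id <- geneId[inAbs[, 1]]

  new("GenomeModel", genes = genes, exons = exons, introns = introns,
      fragments = frags, chromLengths = chromLengths)
}
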