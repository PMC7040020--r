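#' Consensus regions across replicate peak sets
#'
#' Merges overlapping intervals across all replicate region sets and keeps
#' merged intervals supported by at least \code{minSupport} distinct
#' replicates. The output is sorted and non-overlapping; running the
#' function on its own output with \code{minSupport = 1} returns it
#' unchanged.
#'
#' @param replicateRegions list of \code{GRanges}, one per replicate.
#' @param minSupport minimal number of replicates that must contribute at
#'   least one interval to a merged region (default 2).
#' @return \code{GRanges} with a \code{region_id} and \code{support}
#'   column.
#' @export
#' @examples
#' r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 199))
#' r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 249))
#' consensusRegions(list(r1, r2), minSupport = 2)
consensusRegions <- function(replicateRegions, minSupport = 2L) {
  if (!length(replicateRegions)) stop("at least one replicate set required")
  pooled <- do.call(c, lapply(replicateRegions, granges))
  merged <- reduce(GenomicRanges::sort(pooled))
  support <- vapply(replicateRegions, function(r)
    overlapsAny(merged, r), logical(length(merged)))
  support <- if (length(merged) == 1L) sum(support) else rowSums(support)
  out <- merged[support >= minSupport]
  mcols(out)$support <- support[support >= minSupport]
  mcols(out)$region_id <- sprintf("cons%05d", seq_along(out))
  names(out) <- mcols(out)$region_id
  out
}

#' Differential enrichment of consensus regions
#'
#' Thin wrapper chaining \code{\link{nbWaldTest}}, \code{\link{bhAdjust}}
#' and \code{\link{classifyDE}} on region-level counts with the
#' conventional ChIP thresholds (FDR < 0.05, fold change > |2|).
#' \code{"up"} calls are enriched in the non-reference condition,
#' \code{"down"} calls depleted.
#'
#' @param counts region-level count matrix or \code{SummarizedExperiment};
#'   rownames must be region ids.
#' @param condition,reference see \code{\link{nbWaldTest}}.
#' @param fdr FDR cutoff (default 0.05).
#' @param fc fold-change cutoff on the natural scale (default 2).
#' @return list as from \code{\link{classifyDE}}: \code{results} with
#'   per-region calls and \code{tierCounts}.
#' @export
differentialRegions <- function(counts, condition = NULL, reference = NULL,
                                fdr = 0.05, fc = 2) {
  res <- nbWaldTest(counts, condition, reference)
  classifyDE(res, fdr = fdr, fcTiers = fc)
}

#' Annotate regions by genomic category
#'
#' Assigns each region exactly one of five categories by the position of
#' its midpoint, with precedence promoter > tts > exonic > intronic >
#' intergenic. The promoter window is -1000 to +100 bp around the TSS and
#' the TTS window -100 to +1000 bp around the transcription end site, both
#' strand-aware (negative offsets are upstream on the gene's strand). When
#' a midpoint falls into several genes' windows the nearest TSS wins, ties
#' broken by lexicographically smallest gene id.
#'
#' @param regions \code{GRanges} of regions (a \code{region_id} column is
#'   carried through if present).
#' @param genome a \code{\linkS4class{GenomeModel}}.
#' @param promoterWindow integer length-2, offsets of the promoter window
#'   relative to the TSS (default \code{c(-1000, 100)}).
#' @param ttsWindow offsets of the TTS window relative to the gene end
#'   (default \code{c(-100, 1000)}).
#' @return data.frame: \code{region_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{midpoint}, \code{category}, \code{nearest_gene}.
#' @export
annotateRegions <- function(regions, genome,
                            promoterWindow = c(-1000L, 100L),
                            ttsWindow = c(-100L, 1000L)) {
  chroms <- unique(as.character(seqnames(regions)))
  unknown <- setdiff(chroms, names(genome@chromLengths))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  genes <- geneRanges(genome)
  gneg <- as.character(strand(genes)) == "-"
  tss <- ifelse(gneg, end(genes), start(genes))
  tes <- ifelse(gneg, start(genes), end(genes))
  geneId <- mcols(genes)$gene_id

  mid <- (start(regions) + end(regions)) %/% 2L
  midGR <- GRanges(seqnames(regions), IRanges(mid, width = 1L))

  # strand-aware windows: offsets are along the gene's strand
  winGR <- function(anchor, win) {
    lo <- ifelse(gneg, anchor - win[2], anchor + win[1])
    hi <- ifelse(gneg, anchor - win[1], anchor + win[2])
    GRanges(seqnames(genes), IRanges(pmin(lo, hi), pmax(lo, hi)))
  }
  promGR <- winGR(tss, promoterWindow)
  ttsGR <- winGR(tes, ttsWindow)

  n <- length(regions)
  category <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)

  # assign `label` to still-unassigned regions whose midpoint falls in a
  # window; several candidate genes: nearest TSS, ties by smallest gene id
  assignPart <- function(partGR, partGene, label, remaining) {
    ov <- findOverlaps(midGR[remaining], partGR)
    if (!length(ov)) return(remaining)
    qh <- remaining[queryHits(ov)]
    g <- partGene[subjectHits(ov)]
    anchorPos <- tss[match(g, geneId)]
    d <- abs(mid[qh] - anchorPos)
    ord <- order(qh, d, g)
    first <- !duplicated(qh[ord])
    sel <- qh[ord][first]
    category[sel] <<- label
    nearest[sel] <<- g[ord][first]
    setdiff(remaining, sel)
  }
  remaining <- seq_len(n)
  remaining <- assignPart(promGR, geneId, "promoter", remaining)
  remaining <- assignPart(ttsGR, geneId, "tts", remaining)
  remaining <- assignPart(exonRanges(genome),
                          mcols(exonRanges(genome))$gene_id,
                          "exonic", remaining)
  remaining <- assignPart(intronRanges(genome),
                          mcols(intronRanges(genome))$gene_id,
                          "intronic", remaining)

  # intergenic regions: nearest gene by TSS distance on the same chromosome
  if (length(remaining)) {
    for (chr in unique(as.character(seqnames(midGR))[remaining])) {
      ri <- remaining[as.character(seqnames(midGR))[remaining] == chr]
      gi <- which(as.character(seqnames(genes)) == chr)
      if (!length(gi)) next
      nearest[ri] <- geneId[gi][
        vapply(mid[ri], function(x) which.min(abs(tss[gi] - x)), integer(1))]
    }
  }

  rid <- if ("region_id" %in% colnames(mcols(regions)))
    mcols(regions)$region_id else sprintf("region%05d", seq_len(n))
  data.frame(region_id = rid,
             chrom = as.character(seqnames(regions)),
             start = start(regions), end = end(regions), midpoint = mid,
             category = factor(category, levels = c(
               "promoter", "tts", "exonic", "intronic", "intergenic")),
             nearest_gene = nearest, stringsAsFactors = FALSE)
}

#' Test for a shift in the genomic-category distribution
#'
#' Pearson chi-squared test of whether differential regions distribute
#' across the five genomic categories (promoter, tts, exonic, intronic,
#' intergenic) as the background does: expected counts are the background
#' proportions scaled to the differential total, giving 4 degrees of
#' freedom. The test is invariant to scaling the background by a positive
#' constant.
#'
#' @param differentialCategories counts over the 5 categories for the
#'   differential set.
#' @param backgroundCategories counts over the 5 categories for the
#'   background set (must sum to > 0).
#' @return list: \code{statistic}, \code{df} (always 4), \code{pvalue},
#'   \code{expected}, \code{warning} (TRUE when an expected cell < 1).
#' @export
#' @examples
#' distributionShiftTest(c(10, 10, 10, 10, 60), rep(20, 5))  # chisq = 100
distributionShiftTest <- function(differentialCategories,
                                  backgroundCategories) {
  o <- as.numeric(differentialCategories)
  b <- as.numeric(backgroundCategories)
  if (length(o) != 5L || length(b) != 5L)
    stop("both vectors must have length 5 (promoter, tts, exonic, intronic, intergenic)")
  if (sum(b) <= 0) stop("background total must be > 0")
  if (sum(o) == 0)   # an empty differential set trivially matches
    return(list(statistic = 0, df = 4L, pvalue = 1,
                expected = rep(0, 5), warning = FALSE))
  expected <- b / sum(b) * sum(o)
  lowCell <- any(expected < 1)
  if (lowCell)
    warning("expected cell count < 1; chi-squared approximation is weak")
  stat <- sum((o - expected)^2 / expected)
  list(statistic = stat, df = 4L,
       pvalue = pchisq(stat, df = 4L, lower.tail = FALSE),
       expected = expected, warning = lowCell)
}
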