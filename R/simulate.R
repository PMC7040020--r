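#' Configure the synthetic multi-omic generator
#'
#' Returns a validated \code{\linkS4class{SimConfig}}. Defaults describe the
#' emulated study design: two matched conditions with 5 replicates each,
#' negative-binomial counts (variance \eqn{\mu + \phi \mu^2}) with
#' per-sample log-normal library-size factors shared across assays,
#' injected differentially expressed genes (exon+intron), purely
#' post-transcriptional genes (exon only), differential
#' acetylation/occupancy regions with configurable coupling between
#' transcription-factor and acetylation fold changes, distance-decaying
#' promoter contacts with injected alterations, and inverse-usage enhancer
#' pairs.
#'
#' @param nGenes number of genes.
#' @param nChrom number of chromosomes.
#' @param meanFragmentLen mean restriction-fragment length (bp).
#' @param samplesPerCondition replicates per condition (>= 2).
#' @param conditions two condition labels, reference first.
#' @param exonMeanRange log-uniform range of baseline exonic means.
#' @param intronRatio intronic mean as a fraction of the exonic mean.
#' @param rnaDispersionRange log-uniform range of RNA NB dispersions.
#' @param deFraction fraction of genes transcriptionally DE.
#' @param deLog2FCRange magnitude range of injected expression log2 fold
#'   changes (sign random).
#' @param postTxnFraction fraction of genes with an exon-only (post-
#'   transcriptional) change.
#' @param enhancersPerGene mean number of enhancers per gene
#'   (1 + Poisson(mean - 1)).
#' @param nBackgroundRegions acetylated regions not tied to any gene.
#' @param chipMeanRange,chipDispersionRange NB parameter ranges for ChIP
#'   region counts.
#' @param diffPeakFraction overall fraction of differential H3K27Ac regions.
#' @param diffPeakLog2FCRange magnitude range of injected region log2 FCs.
#' @param usageFraction fraction of genes given one up- and one
#'   down-regulated enhancer (differential enhancer usage).
#' @param tfCoupling correlation rho in [0,1] between transcription-factor
#'   and acetylation log2 fold changes at shared regions.
#' @param tfFactors names of the occupancy assays to simulate.
#' @param contactScale expected contact count at the 10 kb reference
#'   distance for unit bias factors.
#' @param decayExponent distance-decay exponent alpha (> 0).
#' @param contactDispersion NB dispersion of contact counts.
#' @param biasSd log-normal sd of bait/other-end bias factors.
#' @param linkEnrichment multiplicative enrichment of designed
#'   enhancer-promoter contacts over the decay background.
#' @param backgroundContactsPerGene extra non-enhancer contacts per bait.
#' @param alteredContactFraction fraction of contacts with an injected
#'   between-condition change.
#' @param alteredContactLog2FCRange magnitude range of injected contact
#'   log2 FCs.
#' @param minAlteredContactMean minimal expected count for a contact to be
#'   eligible for alteration (keeps injected changes above the
#'   mean-count filter of \code{\link{differentialContacts}}).
#' @param sizeFactorSd log-normal sd of per-sample size factors.
#' @param regionSeqLen length (bp) of generated region sequences.
#' @param plantProbDiff,plantProbNull probability of planting the AP-1
#'   consensus in differential / non-differential region sequences.
#' @param seed master seed; every stage derives its own substream from it.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
#' @examples
#' cfg <- simConfig(nGenes = 50, seed = 3)
#' cfg
simConfig <- function(nGenes = 1000L, nChrom = 2L, meanFragmentLen = 4000,
                      samplesPerCondition = 5L,
                      conditions = c("myometrium", "leiomyoma"),
                      exonMeanRange = c(50, 1000), intronRatio = 0.2,
                      rnaDispersionRange = c(0.01, 0.1),
                      deFraction = 0.25, deLog2FCRange = c(1.5, 3),
                      postTxnFraction = 0.05,
                      enhancersPerGene = 3, nBackgroundRegions = 500L,
                      chipMeanRange = c(100, 1000),
                      chipDispersionRange = c(0.01, 0.05),
                      diffPeakFraction = 0.2,
                      diffPeakLog2FCRange = c(1.5, 3),
                      usageFraction = 0.1, tfCoupling = 0.8,
                      tfFactors = c("FOS", "JUN", "CDK8", "MED12"),
                      contactScale = 30, decayExponent = 1,
                      contactDispersion = 0.05, biasSd = 0.2,
                      linkEnrichment = 8, backgroundContactsPerGene = 5L,
                      alteredContactFraction = 0.05,
                      alteredContactLog2FCRange = c(1, 1.5),
                      minAlteredContactMean = 40,
                      sizeFactorSd = 0.15,
                      regionSeqLen = 200L, plantProbDiff = 0.8,
                      plantProbNull = 0.05, seed = 1L) {
  p <- as.list(environment())
  new("SimConfig", params = p)
}

#' @rdname simConfig
#' @param x a \code{SimConfig}.
#' @param name parameter name.
#' @export
setMethod("$", "SimConfig", function(x, name) x@params[[name]])

# per-sample metadata + library-size factors, identical across assays
sampleMeta <- function(config) {
  p <- config@params
  n <- p$samplesPerCondition
  set.seed(subSeed(p$seed, "sizefactors"))
  sf <- exp(rnorm(2L * n, 0, p$sizeFactorSd))
  data.frame(
    sample_id = paste0(rep(c("M", "L"), each = n), seq_len(n)),
    condition = rep(p$conditions, each = n),
    replicate = rep(seq_len(n), 2L),
    sizeFactor = sf,
    stringsAsFactors = FALSE
  )
}

countSE <- function(counts, samples, extraRowData = NULL) {
  cd <- DataFrame(condition = samples$condition,
                  replicate = samples$replicate,
                  row.names = samples$sample_id)
  colnames(counts) <- samples$sample_id
  rd <- if (is.null(extraRowData)) NULL else DataFrame(extraRowData)
  SummarizedExperiment(assays = list(counts = counts), colData = cd,
                       rowData = rd)
}

nbMatrix <- function(meanA, meanB, dispersion, samples) {
  nA <- sum(samples$condition == samples$condition[1])
  mu <- cbind(
    matrix(rep(meanA, nA), ncol = nA),
    matrix(rep(meanB, nrow(samples) - nA), ncol = nrow(samples) - nA)
  )
  mu <- sweep(mu, 2, samples$sizeFactor, "*")
  k <- matrix(rnbinom(length(mu), mu = mu,
                      size = rep(1 / dispersion, ncol(mu))),
              nrow = nrow(mu))
  storage.mode(k) <- "integer"
  k
}

#' Simulate exonic and intronic RNA-seq counts with known truth
#'
#' Draws exon and intron counts per gene from a negative-binomial model.
#' Transcriptionally DE genes receive their injected log2 fold change on
#' exonic AND intronic means; post-transcriptional genes on exonic means
#' only, so exon-intron split analysis can recover them.
#'
#' @param genome a \code{\linkS4class{GenomeModel}}.
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return list with elements \code{exon} and \code{intron}
#'   (\code{SummarizedExperiment}s with a \code{counts} assay), \code{samples}
#'   (sample sheet) and \code{truth} (\code{\linkS4class{SyntheticTruth}}
#'   with gene labels filled in).
#' @export
#' @examples
#' gm <- buildGenome(1, 20, 4000, seed = 1)
#' rna <- simulateRnaseq(gm, simConfig(nGenes = 20, seed = 1))
#' table(truthTable(rna$truth, "genes")$deDirection)
simulateRnaseq <- function(genome, config) {
  p <- config@params
  if (p$samplesPerCondition < 2L)
    stop("at least 2 samples per condition are required")
  samples <- sampleMeta(config)
  set.seed(subSeed(p$seed, "rnaseq"))
  geneId <- mcols(geneRanges(genome))$gene_id
  n <- length(geneId)

  exonMean <- rlogunif(n, p$exonMeanRange[1], p$exonMeanRange[2])
  intronMean <- exonMean * p$intronRatio
  disp <- rlogunif(n, p$rnaDispersionRange[1], p$rnaDispersionRange[2])

  u <- runif(n)
  de <- u < p$deFraction
  postTxn <- !de & u < p$deFraction + p$postTxnFraction
  dirn <- ifelse(de | postTxn, sample(c(-1, 1), n, replace = TRUE), 0)
  lfc <- dirn * runif(n, p$deLog2FCRange[1], p$deLog2FCRange[2])

  exonB <- exonMean * 2^lfc            # DE and post-txn genes: exon shifts
  intronB <- intronMean * 2^(lfc * de) # only DE genes shift intronic means

  exonCounts <- nbMatrix(exonMean, exonB, disp, samples)
  intronCounts <- nbMatrix(intronMean, intronB, disp, samples)
  rownames(exonCounts) <- rownames(intronCounts) <- geneId

  truth <- new("SyntheticTruth",
    genes = data.frame(gene_id = geneId,
                       deDirection = as.integer(dirn * de),
                       log2FC = lfc, postTxn = postTxn,
                       usage = FALSE, stringsAsFactors = FALSE),
    regions = data.frame(), contacts = data.frame(), links = data.frame())
  list(exon = countSE(exonCounts, samples),
       intron = countSE(intronCounts, samples),
       samples = samples, truth = truth)
}

# place one set of region intervals, sorted, with ids
makeRegionGRanges <- function(chrom, start, end, prefix) {
  gr <- GRanges(chrom, IRanges(start, end))
  gr <- GenomicRanges::sort(gr)
  mcols(gr)$region_id <- sprintf("%s%05d", prefix, seq_along(gr))
  names(gr) <- mcols(gr)$region_id
  gr
}

#' Simulate ChIP-seq region tables and counts with coupled fold changes
#'
#' Builds an H3K27Ac region set (promoter regions for every gene, distal
#' enhancer regions linked to genes, plus unlinked background regions) and
#' occupancy assays for the configured transcription factors on a shared
#' subset of the distal regions. Injected transcription-factor log2 fold
#' changes correlate with the H3K27Ac log2 fold changes at shared regions
#' with correlation \code{tfCoupling}; genes flagged for differential
#' enhancer usage receive one enhancer with a positive and one with a
#' negative injected change.
#'
#' @param genome a \code{\linkS4class{GenomeModel}}.
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param truth the \code{\linkS4class{SyntheticTruth}} from
#'   \code{\link{simulateRnaseq}} (gene labels are used to couple enhancer
#'   changes to expression changes).
#' @param assays assay names to generate; must be \code{"H3K27Ac"} and/or
#'   names in \code{config$tfFactors}.
#' @return list: \code{assays} (per assay a list with \code{regions}, a
#'   \code{GRanges} with \code{region_id}, and \code{counts}, a
#'   \code{SummarizedExperiment}), \code{samples}, and the updated
#'   \code{truth} (region labels, designed links, usage flags).
#' @export
simulateChip <- function(genome, config, truth,
                         assays = c("H3K27Ac", config$tfFactors)) {
  p <- config@params
  known <- c("H3K27Ac", p$tfFactors)
  if (!all(assays %in% known))
    stop("unknown assay name(s): ",
         paste(setdiff(assays, known), collapse = ", "))
  samples <- sampleMeta(config)
  set.seed(subSeed(p$seed, "chip"))

  genes <- geneRanges(genome)
  geneId <- mcols(genes)$gene_id
  tss <- tssPositions(genome)
  geneChrom <- as.character(seqnames(genes))
  chromLen <- genome@chromLengths
  n <- length(geneId)
  bm <- baitMap(genome)
  baitOf <- setNames(bm$bait_frag_id, bm$gene_id)

  # promoter regions (~800 bp straddling the TSS)
  promStart <- pmax(1L, tss - 500L + as.integer(runif(n, -100, 100)))
  promEnd <- pmin(chromLen[geneChrom], promStart + 799L)

  # enhancer regions: distal (10 kb - 500 kb), outside promoter windows,
  # in a different fragment than the gene's bait
  nEnh <- 1L + rpois(n, max(p$enhancersPerGene - 1, 0))
  enhGene <- rep(seq_len(n), nEnh)
  m <- length(enhGene)
  drawPos <- function(idx) {
    d <- rlogunif(length(idx), 1e4, 5e5) * sample(c(-1, 1), length(idx), TRUE)
    pos <- tss[idx] + as.integer(d)
    pmin(pmax(pos, 1000L), chromLen[geneChrom[idx]] - 3000L)
  }
  enhMid <- drawPos(enhGene)
  # rejection passes: keep enhancer midpoints out of all promoter windows
  # and out of the owning gene's bait fragment
  promWin <- GRanges(geneChrom, IRanges(pmax(1L, tss - 1500L), tss + 1500L))
  fragIdOfPos <- function(chrom, pos) {
    ov <- findOverlaps(GRanges(chrom, IRanges(pos, width = 1L)),
                       fragments(genome), select = "first")
    mcols(fragments(genome))$frag_id[ov]
  }
  # each designed enhancer gets a fragment of its own: outside promoter
  # windows, outside the owning gene's bait fragment, and not shared with
  # any other designed enhancer (so fragment-level linking is unambiguous
  # for the designed truth)
  enhFrag <- rep(NA_character_, m)
  for (pass in 1:8) {
    hitProm <- !is.na(findOverlaps(
      GRanges(geneChrom[enhGene], IRanges(enhMid, width = 1L)),
      promWin, select = "first"))
    enhFrag <- fragIdOfPos(geneChrom[enhGene], enhMid)
    sameFrag <- enhFrag == unname(baitOf[geneId[enhGene]])
    shared <- duplicated(enhFrag) | duplicated(enhFrag, fromLast = TRUE)
    collide <- shared & duplicated(enhFrag)
    bad <- which(hitProm | sameFrag | collide)
    if (!length(bad)) break
    enhMid[bad] <- drawPos(enhGene[bad])
  }
  enhFrag <- fragIdOfPos(geneChrom[enhGene], enhMid)
  # clip each enhancer region to its fragment so it maps to exactly it
  fr <- fragments(genome)
  fi <- match(enhFrag, mcols(fr)$frag_id)
  enhW <- as.integer(rlogunif(m, 500, 2000))
  enhStart <- pmax(start(fr)[fi], enhMid - enhW %/% 2L)
  enhEnd <- pmin(end(fr)[fi], enhStart + enhW - 1L)

  # unlinked background regions
  nb <- p$nBackgroundRegions
  bgChrom <- sample(names(chromLen), nb, replace = TRUE)
  bgStart <- as.integer(runif(nb, 1000, chromLen[bgChrom] - 4000))
  bgEnd <- bgStart + as.integer(rlogunif(nb, 500, 2000))

  allChrom <- c(geneChrom, geneChrom[enhGene], bgChrom)
  allStart <- c(promStart, enhStart, bgStart)
  allEnd <- c(promEnd, enhEnd, bgEnd)
  kind <- c(rep("promoter", n), rep("enhancer", m), rep("background", nb))
  owner <- c(geneId, geneId[enhGene], rep(NA_character_, nb))
  ord <- order(factor(allChrom, levels = names(chromLen)), allStart)
  regions <- makeRegionGRanges(allChrom[ord], allStart[ord], allEnd[ord],
                               "k27_")
  kind <- kind[ord]; owner <- owner[ord]
  regionId <- mcols(regions)$region_id
  nr <- length(regions)

  # --- injected acetylation log2 fold changes ----------------------------
  lfc <- numeric(nr)
  differential <- logical(nr)
  gtruth <- truth@genes
  usageRole <- rep("none", nr)

  # usage genes: one up- and one down-enhancer among genes with >= 2
  eligible <- which(nEnh >= 2L)
  nUse <- min(round(p$usageFraction * n), length(eligible))
  useGenes <- if (nUse > 0) sample(eligible, nUse) else integer(0)
  for (gi in useGenes) {
    ridx <- which(kind == "enhancer" & owner == geneId[gi])
    pick <- sample(ridx, 2L)
    f <- runif(2, p$diffPeakLog2FCRange[1], p$diffPeakLog2FCRange[2])
    lfc[pick] <- c(f[1], -f[2])
    differential[pick] <- TRUE
    usageRole[pick] <- c("up", "down")
  }
  gtruth$usage[match(geneId[useGenes], gtruth$gene_id)] <- TRUE

  # expression-coupled enhancer and promoter changes for DE genes
  deGenes <- gtruth$gene_id[gtruth$deDirection != 0]
  deSign <- setNames(gtruth$deDirection, gtruth$gene_id)
  cand <- which(kind != "background" & !differential & owner %in% deGenes)
  coupled <- cand[runif(length(cand)) < 0.5]
  lfc[coupled] <- deSign[owner[coupled]] *
    runif(length(coupled), p$diffPeakLog2FCRange[1], p$diffPeakLog2FCRange[2])
  differential[coupled] <- TRUE

  # top up to the target overall differential fraction with random distal
  # regions (acetylation changes concentrate away from promoters); within
  # a gene the injected direction is coherent, mirroring the observed
  # coordination of enhancer changes with their gene -- only designated
  # usage genes carry inverse pairs
  deficit <- round(p$diffPeakFraction * nr) - sum(differential)
  if (deficit > 0) {
    pool <- which(!differential & usageRole == "none" & kind != "promoter")
    extra <- sample(pool, min(deficit, length(pool)))
    geneSign <- setNames(ifelse(gtruth$deDirection != 0,
                                gtruth$deDirection,
                                sample(c(-1, 1), nrow(gtruth), TRUE)),
                         gtruth$gene_id)
    sgn <- ifelse(is.na(owner[extra]),
                  sample(c(-1, 1), length(extra), TRUE),
                  geneSign[owner[extra]])
    lfc[extra] <- sgn *
      runif(length(extra), p$diffPeakLog2FCRange[1], p$diffPeakLog2FCRange[2])
    differential[extra] <- TRUE
  }

  # --- counts ------------------------------------------------------------
  baseMean <- rlogunif(nr, p$chipMeanRange[1], p$chipMeanRange[2])
  disp <- rlogunif(nr, p$chipDispersionRange[1], p$chipDispersionRange[2])
  out <- list()
  regionTruth <- list()
  if ("H3K27Ac" %in% assays) {
    counts <- nbMatrix(baseMean, baseMean * 2^lfc, disp, samples)
    rownames(counts) <- regionId
    mcols(regions)$summit <- (start(regions) + end(regions)) %/% 2L -
      start(regions)
    mcols(regions)$assay <- "H3K27Ac"
    out$H3K27Ac <- list(regions = regions, counts = countSE(counts, samples))
    regionTruth$H3K27Ac <- data.frame(
      region_id = regionId, assay = "H3K27Ac", log2FC = lfc,
      differential = differential,
      direction = sign(lfc) * differential, stringsAsFactors = FALSE)
  }

  # transcription factors: shared subset of distal regions, coupled lfcs
  distal <- which(kind != "promoter")
  zAcet <- (lfc - mean(lfc[distal])) / max(stats::sd(lfc[distal]), 1e-8)
  for (tf in intersect(assays, p$tfFactors)) {
    set.seed(subSeed(p$seed, paste0("chip_", tf)))
    sub <- sort(sample(distal, round(0.7 * length(distal))))
    sdT <- stats::sd(lfc[distal])
    shift <- if (tf %in% c("FOS", "JUN")) -0.4 else 0
    tfLfc <- p$tfCoupling * zAcet[sub] * sdT +
      sqrt(1 - p$tfCoupling^2) * rnorm(length(sub)) * sdT + shift
    tfRegions <- regions[sub]
    tfId <- sub("k27_", paste0(tolower(tf), "_"),
                mcols(tfRegions)$region_id)
    mcols(tfRegions)$region_id <- tfId
    mcols(tfRegions)$assay <- tf
    names(tfRegions) <- tfId
    tfBase <- rlogunif(length(sub), p$chipMeanRange[1], p$chipMeanRange[2])
    tfDisp <- rlogunif(length(sub), p$chipDispersionRange[1],
                       p$chipDispersionRange[2])
    counts <- nbMatrix(tfBase, tfBase * 2^tfLfc, tfDisp, samples)
    rownames(counts) <- tfId
    out[[tf]] <- list(regions = tfRegions,
                      counts = countSE(counts, samples))
    regionTruth[[tf]] <- data.frame(
      region_id = tfId, assay = tf, log2FC = tfLfc,
      differential = abs(tfLfc) >= 1,
      direction = sign(tfLfc) * (abs(tfLfc) >= 1),
      k27_region_id = mcols(regions)$region_id[sub],
      stringsAsFactors = FALSE)
  }

  enhIdx <- which(kind == "enhancer")
  links <- data.frame(gene_id = owner[enhIdx],
                      region_id = regionId[enhIdx],
                      usageRole = usageRole[enhIdx],
                      stringsAsFactors = FALSE)
  rt <- do.call(rbind, lapply(regionTruth, function(d) {
    d$k27_region_id <- if ("k27_region_id" %in% names(d))
      d$k27_region_id else d$region_id
    d
  }))
  rownames(rt) <- NULL
  truth2 <- new("SyntheticTruth", genes = gtruth, regions = rt,
                contacts = truth@contacts, links = links)
  list(assays = out, samples = samples, truth = truth2)
}

#' Construct a ContactSet
#'
#' @param counts integer matrix of contact counts (contacts x samples).
#' @param bait,otherEnd bait and other-end fragment ids.
#' @param distance midpoint-to-midpoint distance in bp (\code{NA} for trans).
#' @param condition per-sample condition labels.
#' @param replicate per-sample replicate numbers.
#' @param contactId optional contact ids (default \code{ct000001} ...).
#' @return a \code{\linkS4class{ContactSet}}.
#' @export
#' @examples
#' cs <- contactSet(matrix(rpois(8, 20), 2), c("f1", "f2"), c("f3", "f4"),
#'                  c(5e4, 8e4), condition = rep(c("A", "B"), each = 2))
#' cs
contactSet <- function(counts, bait, otherEnd, distance, condition,
                       replicate = NULL, contactId = NULL) {
  counts <- as.matrix(counts)
  if (is.null(contactId))
    contactId <- sprintf("ct%06d", seq_len(nrow(counts)))
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  rd <- DataFrame(contact_id = contactId, bait_frag_id = bait,
                  otherend_frag_id = otherEnd, distance = distance)
  rownames(counts) <- contactId
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(condition, "_", replicate)
  se <- SummarizedExperiment(
    assays = list(counts = counts), rowData = rd,
    colData = DataFrame(condition = condition, replicate = replicate,
                        row.names = colnames(counts)))
  new("ContactSet", se)
}

#' Simulate promoter-capture contact counts with distance decay
#'
#' Expected counts follow a power-law distance decay
#' \eqn{\mu(d) \propto d^{-\alpha}} multiplied by log-normal bait and
#' other-end bias factors. Every designed enhancer-gene link from the truth
#' object receives a contact enriched \code{linkEnrichment}-fold over the
#' background; additional background contacts are added per bait. A
#' configurable fraction of sufficiently strong contacts gets an injected
#' between-condition change (usage-designated enhancer contacts are kept
#' stable).
#'
#' @inheritParams simulateChip
#' @param regions the H3K27Ac region \code{GRanges} from
#'   \code{\link{simulateChip}} (used to locate enhancer fragments).
#' @return list: \code{contacts} (a \code{\linkS4class{ContactSet}}),
#'   \code{samples}, and the updated \code{truth} with contact labels and
#'   fragment-resolved links.
#' @export
simulateContacts <- function(genome, config, truth, regions) {
  p <- config@params
  if (p$decayExponent <= 0) stop("decayExponent must be > 0")
  samples <- sampleMeta(config)
  set.seed(subSeed(p$seed, "contacts"))

  frags <- fragments(genome)
  fragId <- mcols(frags)$frag_id
  fragMid <- (start(frags) + end(frags)) / 2
  names(fragMid) <- fragId
  fragChrom <- setNames(as.character(seqnames(frags)), fragId)
  bm <- baitMap(genome)
  baitOf <- setNames(bm$bait_frag_id, bm$gene_id)

  links <- truth@links
  # fragment of each linked enhancer region (midpoint rule)
  mid <- (start(regions) + end(regions)) %/% 2L
  ov <- findOverlaps(GRanges(seqnames(regions), IRanges(mid, width = 1L)),
                     frags, select = "first")
  enhFragOfRegion <- setNames(fragId[ov], mcols(regions)$region_id)
  links$enhancer_frag_id <- unname(enhFragOfRegion[links$region_id])
  links$bait_frag_id <- unname(baitOf[links$gene_id])

  linkKey <- paste(links$bait_frag_id, links$enhancer_frag_id)
  linkPairs <- !duplicated(linkKey)
  lb <- links$bait_frag_id[linkPairs]
  lo <- links$enhancer_frag_id[linkPairs]

  # background contacts: random fragments near each bait
  nbg <- p$backgroundContactsPerGene
  baitIdx <- match(bm$bait_frag_id, fragId)
  bgBaitIdx <- rep(baitIdx, nbg)
  off <- sample(c(-1, 1), length(bgBaitIdx), TRUE) *
    pmax(3L, as.integer(rlogunif(length(bgBaitIdx), 3, 250)))
  bgOeIdx <- pmin(pmax(bgBaitIdx + off, 1L), length(frags))
  keep <- fragChrom[bgOeIdx] == fragChrom[bgBaitIdx] & bgOeIdx != bgBaitIdx
  bgB <- fragId[bgBaitIdx[keep]]
  bgO <- fragId[bgOeIdx[keep]]

  bait <- c(lb, bgB)
  oe <- c(lo, bgO)
  isLink <- c(rep(TRUE, length(lb)), rep(FALSE, length(bgB)))
  dup <- duplicated(paste(bait, oe))
  bait <- bait[!dup]; oe <- oe[!dup]; isLink <- isLink[!dup]
  ok <- !is.na(bait) & !is.na(oe) & bait != oe
  bait <- bait[ok]; oe <- oe[ok]; isLink <- isLink[ok]

  distance <- abs(fragMid[bait] - fragMid[oe])

  # bias factors per fragment role
  uf <- unique(c(bait, oe))
  baitBias <- setNames(exp(rnorm(length(uf), 0, p$biasSd)), uf)
  oeBias <- setNames(exp(rnorm(length(uf), 0, p$biasSd)), uf)
  mu <- p$contactScale * (distance / 1e4)^(-p$decayExponent) *
    baitBias[bait] * oeBias[oe] * ifelse(isLink, p$linkEnrichment, 1)

  # injected alterations among strong, non-usage contacts
  usageFrag <- unique(links$enhancer_frag_id[links$usageRole != "none"])
  eligible <- which(mu >= p$minAlteredContactMean & !(oe %in% usageFrag))
  nAlt <- min(round(p$alteredContactFraction * length(mu)), length(eligible))
  altIdx <- if (nAlt > 0) sample(eligible, nAlt) else integer(0)
  altLfc <- numeric(length(mu))
  altLfc[altIdx] <- sample(c(-1, 1), nAlt, TRUE) *
    runif(nAlt, p$alteredContactLog2FCRange[1],
          p$alteredContactLog2FCRange[2])

  counts <- nbMatrix(mu, mu * 2^altLfc,
                     rep(p$contactDispersion, length(mu)), samples)
  colnames(counts) <- samples$sample_id
  cs <- contactSet(counts, unname(bait), unname(oe), unname(distance),
                   condition = samples$condition,
                   replicate = samples$replicate)
  contactId <- rowData(cs)$contact_id

  pairKey <- paste(bait, oe)
  links$contact_id <- contactId[match(
    paste(links$bait_frag_id, links$enhancer_frag_id), pairKey)]
  contactTruth <- data.frame(
    contact_id = contactId, altered = altLfc != 0,
    direction = sign(altLfc), log2FC = altLfc,
    isLink = isLink, expected = unname(mu), stringsAsFactors = FALSE)

  truth2 <- new("SyntheticTruth", genes = truth@genes,
                regions = truth@regions, contacts = contactTruth,
                links = links)
  list(contacts = cs, samples = samples, truth = truth2)
}

#' Generate region sequences with planted AP-1 motifs
#'
#' Synthetic-mode stand-in for fetching genomic sequence: each region gets
#' an i.i.d. background sequence; differential regions (per truth) receive
#' the AP-1 consensus \code{TGACTCA} planted near the region centre with
#' probability \code{plantProbDiff}, non-differential regions with
#' probability \code{plantProbNull}.
#'
#' @param regions \code{GRanges} with a \code{region_id} column.
#' @param truth a \code{\linkS4class{SyntheticTruth}} with region labels.
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return named character vector of sequences.
#' @export
simulateRegionSequences <- function(regions, truth, config) {
  p <- config@params
  set.seed(subSeed(p$seed, "sequences"))
  ids <- mcols(regions)$region_id
  rt <- truth@regions
  diff <- setNames(rep(FALSE, length(ids)), ids)
  hit <- rt$region_id %in% ids
  diff[rt$region_id[hit]] <- rt$differential[hit]
  L <- p$regionSeqLen
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_along(ids), function(i)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  motif <- "TGACTCA"
  plant <- runif(length(ids)) <
    ifelse(diff, p$plantProbDiff, p$plantProbNull)
  offs <- as.integer(L / 2 - nchar(motif) / 2 +
                       round(runif(length(ids), -20, 20)))
  for (i in which(plant)) {
    substr(seqs[i], offs[i], offs[i] + nchar(motif) - 1L) <- motif
  }
  names(seqs) <- ids
  seqs
}

#' Simulate a complete matched two-condition multi-omic dataset
#'
#' Convenience driver chaining \code{\link{buildGenome}},
#' \code{\link{simulateRnaseq}}, \code{\link{simulateChip}},
#' \code{\link{simulateContacts}} and
#' \code{\link{simulateRegionSequences}}. Each stage draws from its own
#' seed substream, so the result is reproducible and stages do not perturb
#' one another.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return list with \code{genome}, \code{samples}, \code{rna} (exon and
#'   intron \code{SummarizedExperiment}s), \code{chip} (per-assay regions
#'   and counts), \code{contacts} (\code{\linkS4class{ContactSet}}),
#'   \code{sequences}, and \code{truth}.
#' @export
#' @examples
#' sim <- simulateDataset(simConfig(nGenes = 30, seed = 2))
#' sim$truth
simulateDataset <- function(config) {
  p <- config@params
  genome <- buildGenome(p$nChrom, p$nGenes, p$meanFragmentLen, p$seed)
  rna <- simulateRnaseq(genome, config)
  chip <- simulateChip(genome, config, rna$truth)
  k27 <- chip$assays$H3K27Ac$regions
  con <- simulateContacts(genome, config, chip$truth, k27)
  seqs <- simulateRegionSequences(k27, con$truth, config)
  list(genome = genome, samples = rna$samples,
       rna = rna[c("exon", "intron")], chip = chip$assays,
       contacts = con$contacts, sequences = seqs, truth = con$truth)
}
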