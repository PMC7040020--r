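#' @include AllClasses.R
NULL

#' Accessors for GenomeModel and ContactSet objects
#'
#' \code{fragments} returns the restriction-fragment map, \code{geneRanges}
#' the gene bodies, \code{exonRanges}/\code{intronRanges} the exonic and
#' intronic intervals, \code{tssPositions} the strand-aware transcription
#' start sites, and \code{baitMap} the gene to bait-fragment assignment
#' (the fragment containing each TSS). For \code{ContactSet},
#' \code{contactDistance}, \code{baitFrags} and \code{otherEndFrags} expose
#' the corresponding rowData columns.
#'
#' @param x a \code{GenomeModel} or \code{ContactSet}.
#' @return A \code{GRanges}, named vector or data.frame, as described.
#' @name genome-accessors
#' @aliases fragments geneRanges exonRanges intronRanges tssPositions
#'   baitMap contactDistance baitFrags otherEndFrags
#' @examples
#' gm <- buildGenome(nChrom = 1, nGenes = 5, meanFragmentLen = 2000, seed = 1)
#' fragments(gm)
#' head(tssPositions(gm))
NULL

#' @rdname genome-accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname genome-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname genome-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname genome-accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))
#' @rdname genome-accessors
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))
#' @rdname genome-accessors
#' @export
setGeneric("baitMap", function(x) standardGeneric("baitMap"))
#' @rdname genome-accessors
#' @export
setGeneric("contactDistance", function(x) standardGeneric("contactDistance"))
#' @rdname genome-accessors
#' @export
setGeneric("baitFrags", function(x) standardGeneric("baitFrags"))
#' @rdname genome-accessors
#' @export
setGeneric("otherEndFrags", function(x) standardGeneric("otherEndFrags"))

#' @rdname genome-accessors
setMethod("fragments", "GenomeModel", function(x) x@fragments)
#' @rdname genome-accessors
setMethod("geneRanges", "GenomeModel", function(x) x@genes)
#' @rdname genome-accessors
setMethod("exonRanges", "GenomeModel", function(x) x@exons)
#' @rdname genome-accessors
setMethod("intronRanges", "GenomeModel", function(x) x@introns)

#' @rdname genome-accessors
setMethod("tssPositions", "GenomeModel", function(x) {
  g <- x@genes
  pos <- ifelse(as.character(strand(g)) == "-", end(g), start(g))
  setNames(pos, mcols(g)$gene_id)
})

#' @rdname genome-accessors
setMethod("baitMap", "GenomeModel", function(x) {
  g <- x@genes
  tss <- tssPositions(x)
  q <- GRanges(seqnames(g), IRanges(tss, width = 1L))
  ov <- findOverlaps(q, x@fragments)
  df <- data.frame(
    gene_id = mcols(g)$gene_id[queryHits(ov)],
    bait_frag_id = mcols(x@fragments)$frag_id[subjectHits(ov)],
    stringsAsFactors = FALSE
  )
  df[!duplicated(df$gene_id), , drop = FALSE]
})

#' @rdname genome-accessors
setMethod("contactDistance", "ContactSet",
          function(x) rowData(x)$distance)
#' @rdname genome-accessors
setMethod("baitFrags", "ContactSet",
          function(x) rowData(x)$bait_frag_id)
#' @rdname genome-accessors
setMethod("otherEndFrags", "ContactSet",
          function(x) rowData(x)$otherend_frag_id)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(object@chromLengths), "chromosome(s),",
      length(object@genes), "genes,", length(object@fragments),
      "restriction fragments\n")
  cat("  total size:", sum(as.numeric(object@chromLengths)), "bp\n")
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$nGenes, "genes,", p$samplesPerCondition, "vs",
      p$samplesPerCondition, "samples, seed", p$seed, "\n")
  cat("  deFraction", p$deFraction, "| postTxn", p$postTxnFraction,
      "| diffPeak", p$diffPeakFraction, "| alteredContact",
      p$alteredContactFraction, "| usage", p$usageFraction, "\n")
  cat("  tfCoupling", p$tfCoupling, "| decayExponent", p$decayExponent, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@genes), "genes (",
      sum(object@genes$deDirection != 0), "DE,",
      sum(object@genes$postTxn), "post-transcriptional,",
      sum(object@genes$usage), "usage),",
      nrow(object@regions), "region labels,",
      nrow(object@contacts), "contact labels\n")
})

setMethod("show", "Pwm", function(object) {
  cat("Pwm", object@name, ":", ncol(object@probs), "positions, threshold",
      round(object@threshold, 2), "\n")
})

#' Extract ground-truth tables
#'
#' @param x a \code{SyntheticTruth}.
#' @param table one of \code{"genes"}, \code{"regions"}, \code{"contacts"},
#'   \code{"links"}.
#' @return the requested data.frame of injected labels.
#' @export
#' @examples
#' cfg <- simConfig(nGenes = 20, seed = 1)
#' sim <- simulateDataset(cfg)
#' head(truthTable(sim$truth, "genes"))
truthTable <- function(x, table = c("genes", "regions", "contacts", "links")) {
  stopifnot(is(x, "SyntheticTruth"))
  table <- match.arg(table)
  slot(x, table)
}
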