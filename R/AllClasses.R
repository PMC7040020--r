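#' @include utils.R
NULL

#' GenomeModel: gene annotation plus a restriction-fragment partition
#'
#' Holds a (toy or real) gene annotation together with an ordered
#' restriction-fragment map that partitions every chromosome. Ranges are
#' stored in the native \code{GRanges} convention (1-based, closed);
#' on-disk BED I/O is 0-based half-open (see \code{\link{readBed}}).
#'
#' @slot genes \code{GRanges} of gene bodies with metadata column
#'   \code{gene_id}; the TSS is the strand-aware 5' end.
#' @slot exons \code{GRanges} of exons with metadata column \code{gene_id}.
#' @slot introns \code{GRanges} of introns with metadata column
#'   \code{gene_id}.
#' @slot fragments \code{GRanges} of restriction fragments with metadata
#'   column \code{frag_id}; within each chromosome the fragments are
#'   disjoint, sorted and tile the chromosome exactly.
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#'
#' @seealso \code{\link{buildGenome}}
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(
    genes = "GRanges",
    exons = "GRanges",
    introns = "GRanges",
    fragments = "GRanges",
    chromLengths = "integer"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  fr <- object@fragments
  for (chr in names(object@chromLengths)) {
    f <- fr[as.character(seqnames(fr)) == chr]
    if (length(f) == 0L) {
      msg <- c(msg, paste0("chromosome ", chr, " has no fragments"))
      next
    }
    o <- order(start(f))
    f <- f[o]
    if (start(f)[1] != 1L)
      msg <- c(msg, paste0("fragments on ", chr, " do not start at 1"))
    if (end(f)[length(f)] != object@chromLengths[[chr]])
      msg <- c(msg, paste0("fragments on ", chr,
                           " do not end at the chromosome length"))
    if (length(f) > 1L && any(start(f)[-1] != end(f)[-length(f)] + 1L))
      msg <- c(msg, paste0("fragments on ", chr, " are not a partition"))
  }
  if (!"gene_id" %in% colnames(mcols(object@genes)))
    msg <- c(msg, "genes must carry a gene_id metadata column")
  if (length(object@exons) && length(object@introns)) {
    ov <- findOverlaps(object@exons, object@introns)
    same <- mcols(object@exons)$gene_id[queryHits(ov)] ==
      mcols(object@introns)$gene_id[subjectHits(ov)]
    if (any(same))
      msg <- c(msg, "exon and intron intervals of a gene must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic multi-omic generator
#'
#' All knobs of the synthetic data generator. Defaults emulate the study
#' design the package targets: 5-vs-5 matched tissue replicates, a
#' negative-binomial count model with per-sample library-size factors,
#' distance-decaying promoter contacts with bait/other-end biases, and
#' injected differential features with known direction and effect size.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateDataset}}
#' @exportClass SimConfig
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- character()
  fr <- c("deFraction", "postTxnFraction", "diffPeakFraction",
          "alteredContactFraction", "usageFraction", "tfCoupling")
  for (f in fr) if (p[[f]] < 0 || p[[f]] > 1)
    msg <- c(msg, paste0(f, " must lie in [0, 1]"))
  if (any(unlist(p[c("rnaDispersionRange", "chipDispersionRange",
                     "contactDispersion")]) <= 0))
    msg <- c(msg, "dispersions must be > 0")
  if (p$decayExponent <= 0) msg <- c(msg, "decayExponent must be > 0")
  if (p$samplesPerCondition < 2)
    msg <- c(msg, "at least 2 samples per condition are required")
  if (p$nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (p$meanFragmentLen < 200)
    msg <- c(msg, "meanFragmentLen must be >= 200")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground-truth labels of a simulated dataset
#'
#' Records every injected effect so downstream calls can be scored for
#' sensitivity and false discovery: per-gene expression labels, per-region
#' acetylation/occupancy labels, per-contact alteration labels and the
#' designed enhancer-gene links.
#'
#' @slot genes data.frame: \code{gene_id}, \code{deDirection} (-1/0/+1),
#'   \code{log2FC} (exonic), \code{postTxn}, \code{usage}.
#' @slot regions data.frame: \code{region_id}, \code{assay},
#'   \code{log2FC}, \code{differential}, \code{direction}.
#' @slot contacts data.frame: \code{contact_id}, \code{altered},
#'   \code{direction}, \code{log2FC}.
#' @slot links data.frame of designed enhancer-gene links:
#'   \code{gene_id}, \code{region_id}, \code{usageRole}
#'   ("up"/"down"/"none").
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(genes = "data.frame", regions = "data.frame",
                 contacts = "data.frame", links = "data.frame")
)

setValidity("SyntheticTruth", function(object) {
  g <- object@genes
  msg <- character()
  if (nrow(g) && any(g$deDirection != 0 & g$postTxn))
    msg <- c(msg, "a gene cannot be both transcriptionally DE and purely post-transcriptional")
  if (nrow(object@links) && !all(object@links$gene_id %in% g$gene_id))
    msg <- c(msg, "truth links refer to unknown gene ids")
  if (length(msg)) msg else TRUE
})

#' ContactSet: bait/other-end contact counts with sample metadata
#'
#' A \code{SummarizedExperiment} whose rows are bait-fragment to
#' other-end-fragment contacts and whose columns are samples. The
#' \code{counts} assay holds nonnegative integer read counts;
#' \code{rowData} carries \code{contact_id}, \code{bait_frag_id},
#' \code{otherend_frag_id} and \code{distance} (midpoint-to-midpoint bp,
#' \code{NA} for trans contacts); \code{colData} carries \code{condition}
#' and \code{replicate}.
#'
#' @seealso \code{\link{contactSet}}, \code{\link{scoreContacts}}
#' @exportClass ContactSet
setClass("ContactSet", contains = "SummarizedExperiment")

setValidity("ContactSet", function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("contact_id", "bait_frag_id", "otherend_frag_id", "distance")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else if (any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (any(rd$bait_frag_id == rd$otherend_frag_id))
    msg <- c(msg, "bait and other-end fragment must differ")
  d <- rd$distance
  if (any(!is.na(d) & d <= 0))
    msg <- c(msg, "cis distances must be > 0")
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'condition'")
  if (length(msg)) msg else TRUE
})

#' Pwm: a position weight matrix with log-odds scores
#'
#' @slot name motif name.
#' @slot probs 4 x L matrix of per-position base probabilities, rows
#'   A, C, G, T; columns sum to 1.
#' @slot background length-4 background base frequencies.
#' @slot logOdds 4 x L log2-odds score matrix.
#' @slot threshold minimal log-odds score for a hit.
#'
#' @seealso \code{\link{pwm}}, \code{\link{scanPwm}}
#' @exportClass Pwm
setClass("Pwm",
  representation(name = "character", probs = "matrix",
                 background = "numeric", logOdds = "matrix",
                 threshold = "numeric")
)

setValidity("Pwm", function(object) {
  msg <- character()
  if (nrow(object@probs) != 4L || ncol(object@probs) < 4L)
    msg <- c(msg, "probs must be a 4 x L matrix with L >= 4")
  if (any(abs(colSums(object@probs) - 1) > 1e-9))
    msg <- c(msg, "each position's probabilities must sum to 1")
  if (length(object@background) != 4L || any(object@background <= 0))
    msg <- c(msg, "background must be 4 positive frequencies")
  if (length(msg)) msg else TRUE
})
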