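#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors by the median-of-ratios
#' method: each sample's counts are divided by the per-feature geometric
#' mean across samples, and the factor is the median of those ratios over
#' features with a positive geometric mean. Factors are rescaled so their
#' geometric mean is exactly 1.
#'
#' @param counts count matrix (features x samples) or
#'   \code{SummarizedExperiment} with a \code{counts} assay.
#' @return named numeric vector of size factors.
#' @export
#' @examples
#' k <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' computeSizeFactors(k)   # (1/sqrt(2), sqrt(2))
computeSizeFactors <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  counts <- as.matrix(counts)
  zeroSample <- colSums(counts) == 0
  if (any(zeroSample))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zeroSample], collapse = ", "))
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no feature has nonzero counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(x)
    exp(median(log(x) - logGeo[use])))
  sf <- sf / exp(mean(log(sf)))
  if (is.null(names(sf))) names(sf) <- colnames(counts)
  sf
}

# variance-stabilized moderated variance machinery shared by nbWaldTest
# and runEisa: per-feature empirical variance of log2(normalized count +
# pseudocount), shrunk halfway (on the variance scale) toward a
# mean-variance trend fitted by binned averaging on log base mean.
trendVar <- function(baseMean, v, nbins = 20L) {
  ok <- is.finite(v) & baseMean > 0
  if (sum(ok) < 10L) {
    tr <- rep(mean(v[ok], na.rm = TRUE), length(v))
    return(pmax(tr, 1e-12))
  }
  lb <- log(baseMean)
  br <- unique(quantile(lb[ok], probs = seq(0, 1, length.out = nbins + 1L)))
  if (length(br) < 3L) {
    tr <- rep(mean(v[ok]), length(v))
    return(pmax(tr, 1e-12))
  }
  bins <- cut(lb, br, include.lowest = TRUE)
  mv <- tapply(v[ok], bins[ok], mean)
  mm <- tapply(lb[ok], bins[ok], mean)
  keep <- is.finite(mv) & is.finite(mm)
  pmax(approx(mm[keep], mv[keep], xout = lb, rule = 2)$y, 1e-12)
}

moderatedGroupStats <- function(q, condA, condB, pseudocount = 0.5,
                                shrinkWeight = 0.5, trend = NULL) {
  y <- log2(q + pseudocount)
  nA <- sum(condA); nB <- sum(condB)
  yA <- rowMeans(y[, condA, drop = FALSE])
  yB <- rowMeans(y[, condB, drop = FALSE])
  vA <- rowVarsBase(y[, condA, drop = FALSE])
  vB <- rowVarsBase(y[, condB, drop = FALSE])
  vPool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  baseMean <- rowMeans(q)
  vTr <- if (is.null(trend)) trendVar(baseMean, vPool) else trend
  vS <- (1 - shrinkWeight) * vPool + shrinkWeight * vTr
  list(lfc = yB - yA, varMean = vS * (1 / nA + 1 / nB),
       baseMean = baseMean, vS = vS, nA = nA, nB = nB)
}

#' Negative-binomial two-condition Wald test
#'
#' Per-feature two-sided Wald test of a between-condition difference on
#' normalized counts. Counts are normalized by median-of-ratios size
#' factors, variance-stabilized with a pseudocount of
#' \code{pseudocount} on the log2 scale, and the per-feature variance is
#' moderated by shrinking it halfway toward a fitted mean-variance trend;
#' the Wald statistic (log2 fold change over its standard error) is
#' referred to the standard normal. Under the negative-binomial model the
#' stabilized-scale variance is \eqn{(\phi + 1/\mu)/\ln(2)^2}, from which a
#' per-feature dispersion estimate is also reported.
#'
#' Features with all-zero counts in both conditions get \code{NA} p-values
#' and are excluded from the BH correction.
#'
#' @param counts count matrix (features x samples) or a
#'   \code{SummarizedExperiment} with \code{counts} assay and a
#'   \code{condition} column in \code{colData}.
#' @param condition per-sample condition labels (two levels); ignored when
#'   \code{counts} is a \code{SummarizedExperiment} carrying them.
#' @param reference reference condition (fold changes are other over
#'   reference); default: first label encountered.
#' @param sizeFactors optional precomputed size factors.
#' @param shrinkWeight weight of the mean-variance trend in the moderated
#'   variance (0 = raw per-feature, 1 = pure trend).
#' @param pseudocount stabilizer added to normalized counts before log2.
#' @param adjust if \code{TRUE} (default) BH-adjusted q-values are added.
#' @return data.frame: \code{feature_id}, \code{baseMean}, \code{log2FC},
#'   \code{lfcSE}, \code{stat}, \code{pvalue}, \code{dispersion}, and
#'   \code{padj} when \code{adjust}.
#' @export
#' @examples
#' set.seed(1)
#' k <- matrix(rnbinom(2000, mu = 100, size = 10), ncol = 10)
#' res <- nbWaldTest(k, rep(c("A", "B"), each = 5))
#' head(res)
nbWaldTest <- function(counts, condition = NULL, reference = NULL,
                       sizeFactors = NULL, shrinkWeight = 0.5,
                       pseudocount = 0.5, adjust = TRUE) {
  rc <- resolveCounts(counts, condition)
  counts <- rc$counts; condition <- rc$condition
  lev <- conditionLevels(condition, reference)
  if (min(table(condition)) < 2L)
    stop("at least 2 samples per condition are required")
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  q <- sweep(counts, 2, sizeFactors, "/")
  st <- moderatedGroupStats(q, condition == lev[1], condition == lev[2],
                            pseudocount, shrinkWeight)
  se <- sqrt(st$varMean)
  z <- st$lfc / se
  p <- 2 * pnorm(-abs(z))
  allZero <- rowSums(counts) == 0
  p[allZero] <- NA_real_
  z[allZero] <- NA_real_
  # implied NB dispersion from the stabilized-scale variance
  meanInvSf <- mean(1 / sizeFactors)
  disp <- pmax(st$vS * log(2)^2 - meanInvSf / pmax(st$baseMean, 1e-8), 1e-8)
  res <- data.frame(
    feature_id = rownames(counts), baseMean = st$baseMean,
    log2FC = st$lfc, lfcSE = se, stat = z, pvalue = p,
    dispersion = disp, stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) res$padj <- bhAdjust(res$pvalue)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up q-values with cumulative-minimum enforcement.
#' \code{NA} p-values are passed through unchanged and excluded from the
#' number of tests.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NAs allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
bhAdjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Classify differential features into fold-change tiers
#'
#' A feature is significant when \code{padj < fdr}; tier-k membership
#' additionally requires \code{|log2FC| > log2(k)}. Tiers nest by
#' construction. The per-feature \code{call} is \code{"up"}/\code{"down"}
#' for features passing the FDR and the first (smallest) fold threshold,
#' otherwise \code{"unchanged"}.
#'
#' @param results data.frame from \code{\link{nbWaldTest}} (needs
#'   \code{log2FC} and \code{padj}).
#' @param fdr FDR threshold.
#' @param fcTiers fold-change thresholds (natural scale), e.g.
#'   \code{c(2, 4)}.
#' @return list: \code{results} (input plus \code{call} and per-tier
#'   logical columns \code{tierK}), \code{tierCounts} (named vector,
#'   including \code{significant} = FDR-only count).
#' @export
#' @examples
#' d <- data.frame(feature_id = "g1", log2FC = 1.5, padj = 0.005)
#' classifyDE(d, fdr = 0.01, fcTiers = c(2, 4))$tierCounts
classifyDE <- function(results, fdr = 0.01, fcTiers = c(2, 4)) {
  stopifnot(all(c("log2FC", "padj") %in% colnames(results)))
  sig <- !is.na(results$padj) & results$padj < fdr
  tiers <- lapply(fcTiers, function(k)
    sig & abs(results$log2FC) > log2(k))
  names(tiers) <- paste0("tier", fcTiers)
  minTier <- if (length(fcTiers)) tiers[[which.min(fcTiers)]] else sig
  results$call <- ifelse(minTier,
                         ifelse(results$log2FC > 0, "up", "down"),
                         "unchanged")
  for (nm in names(tiers)) results[[nm]] <- tiers[[nm]]
  counts <- c(significant = sum(sig), vapply(tiers, sum, integer(1)))
  list(results = results, tierCounts = counts)
}

#' Exon-intron split analysis
#'
#' Separates transcriptional from post-transcriptional regulation by
#' contrasting exonic and intronic fold changes. Exon and intron matrices
#' are normalized independently (median-of-ratios); genes must show a mean
#' normalized exonic AND intronic count of at least \code{floor} in at
#' least one condition to be tested. The exon-minus-intron interaction
#' contrast \eqn{\Delta = \Delta exon - \Delta intron} is tested with a
#' moderated Wald statistic whose variance pools the four
#' assay-by-condition cells under a trend fitted jointly across both
#' assays; genes with \code{padj < eisaFdr} are flagged as
#' post-transcriptionally regulated.
#'
#' @param exonCounts,intronCounts count matrices or
#'   \code{SummarizedExperiment}s sharing gene ids and samples.
#' @param condition per-sample condition labels.
#' @param reference reference condition label.
#' @param eisaFdr FDR threshold for the post-transcriptional flag.
#' @param floor expression filter on mean normalized counts (default 8).
#' @param shrinkWeight trend weight of the moderated variance.
#' @return list: \code{results} data.frame (\code{gene_id},
#'   \code{deltaExon}, \code{deltaIntron}, \code{deltaDiff}, \code{pvalue},
#'   \code{padj}, \code{postTxn}), \code{correlation} (Pearson correlation
#'   of exonic and intronic fold changes across tested genes), and
#'   \code{nFiltered}.
#' @export
runEisa <- function(exonCounts, intronCounts, condition = NULL,
                    reference = NULL, eisaFdr = 0.05, floor = 8,
                    shrinkWeight = 0.5) {
  rcE <- resolveCounts(exonCounts, condition)
  rcI <- resolveCounts(intronCounts, condition)
  if (!identical(dim(rcE$counts), dim(rcI$counts)) ||
      !identical(rcE$condition, rcI$condition))
    stop("exon and intron matrices must share samples and conditions")
  if (!setequal(rownames(rcE$counts), rownames(rcI$counts))) {
    off <- c(setdiff(rownames(rcE$counts), rownames(rcI$counts)),
             setdiff(rownames(rcI$counts), rownames(rcE$counts)))
    stop("mismatched gene sets; offenders: ",
         paste(head(off, 10), collapse = ", "))
  }
  ex <- rcE$counts
  it <- rcI$counts[rownames(ex), , drop = FALSE]
  condition <- rcE$condition
  lev <- conditionLevels(condition, reference)
  A <- condition == lev[1]; B <- condition == lev[2]

  sfE <- computeSizeFactors(ex)
  sfI <- computeSizeFactors(it)
  qE <- sweep(ex, 2, sfE, "/")
  qI <- sweep(it, 2, sfI, "/")

  keep <- (rowMeans(qE[, A, drop = FALSE]) >= floor &
           rowMeans(qI[, A, drop = FALSE]) >= floor) |
          (rowMeans(qE[, B, drop = FALSE]) >= floor &
           rowMeans(qI[, B, drop = FALSE]) >= floor)
  nFiltered <- sum(!keep)
  qE <- qE[keep, , drop = FALSE]
  qI <- qI[keep, , drop = FALSE]

  # joint mean-variance trend across both assays (shared machinery of the
  # combined fit), then per-assay moderated contrasts
  y <- rbind(log2(qE + 0.5), log2(qI + 0.5))
  vPool <- (rowVarsBase(y[, A, drop = FALSE]) * (sum(A) - 1) +
            rowVarsBase(y[, B, drop = FALSE]) * (sum(B) - 1)) /
    (sum(A) + sum(B) - 2)
  baseAll <- rowMeans(rbind(qE, qI))
  vTrAll <- trendVar(baseAll, vPool)
  g <- nrow(qE)
  stE <- moderatedGroupStats(qE, A, B, shrinkWeight = shrinkWeight,
                             trend = vTrAll[seq_len(g)])
  stI <- moderatedGroupStats(qI, A, B, shrinkWeight = shrinkWeight,
                             trend = vTrAll[g + seq_len(g)])
  deltaDiff <- stE$lfc - stI$lfc
  se <- sqrt(stE$varMean + stI$varMean)
  p <- 2 * pnorm(-abs(deltaDiff / se))
  q <- bhAdjust(p)
  res <- data.frame(
    gene_id = rownames(qE), deltaExon = stE$lfc, deltaIntron = stI$lfc,
    deltaDiff = deltaDiff, se = se, pvalue = p, padj = q,
    postTxn = !is.na(q) & q < eisaFdr,
    stringsAsFactors = FALSE, row.names = NULL)
  list(results = res,
       correlation = if (nrow(res) > 2)
         cor(res$deltaExon, res$deltaIntron) else NA_real_,
       nFiltered = nFiltered)
}
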