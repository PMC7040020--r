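#' Construct a position weight matrix
#'
#' Builds a \code{\linkS4class{Pwm}} from per-position base probabilities.
#' Log2-odds scores are computed against the supplied background base
#' frequencies; the default hit threshold is \code{thresholdQuantile}
#' times the maximal attainable score.
#'
#' @param name motif name.
#' @param probs 4 x L probability matrix, rows in order A, C, G, T.
#' @param background length-4 background base frequencies (default
#'   uniform).
#' @param threshold absolute log2-odds threshold; overrides
#'   \code{thresholdQuantile} when given.
#' @param thresholdQuantile fraction of the maximal score used as the
#'   default threshold.
#' @return a \code{\linkS4class{Pwm}}.
#' @export
#' @examples
#' p <- matrix(0.25, 4, 6); p[1, ] <- 0.7; p[2:4, ] <- 0.1
#' pwm("toyA", p)
pwm <- function(name, probs, background = rep(0.25, 4), threshold = NULL,
                thresholdQuantile = 0.8) {
  probs <- as.matrix(probs)
  rownames(probs) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  lo <- log2(probs / background)
  maxScore <- sum(apply(lo, 2, max))
  if (is.null(threshold)) threshold <- thresholdQuantile * maxScore
  new("Pwm", name = name, probs = probs, background = background,
      logOdds = lo, threshold = threshold)
}

#' Default AP-1 position weight matrix
#'
#' A synthetic PWM for the AP-1 TPA-response element TGA(C/G)TCA built
#' from the consensus with 85\% weight on the consensus base (the middle
#' position split between C and G). It is not derived from any measured
#' motif database and is intended for simulated sequences and examples.
#'
#' @param ... passed on to \code{\link{pwm}} (e.g. \code{background},
#'   \code{thresholdQuantile}).
#' @return a \code{\linkS4class{Pwm}} of length 7.
#' @export
defaultAP1Pwm <- function(...) {
  cons <- c("T", "G", "A", "S", "T", "C", "A")
  probs <- matrix(0.05, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) {
    if (cons[j] == "S") {
      probs[, j] <- c(0.05, 0.425, 0.425, 0.10)
    } else {
      probs[cons[j], j] <- 0.85
      probs[setdiff(rownames(probs), cons[j]), j] <- 0.05
    }
  }
  probs <- sweep(probs, 2, colSums(probs), "/")
  pwm("AP1_synthetic", probs, ...)
}

# integer-encode a DNA string: A=1, C=2, G=3, T=4, N/other=0
encodeDNA <- function(s) {
  v <- utf8ToInt(toupper(s))
  out <- integer(length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}

# log-odds scores of every window start on the encoded forward strand;
# unknown bases (0) contribute 0 (background odds)
windowScores <- function(enc, lo) {
  L <- ncol(lo)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    b <- enc[j:(j + n - 1L)]
    add <- numeric(n)
    known <- b > 0L
    add[known] <- lo[cbind(b[known], j)]
    sc <- sc + add
  }
  sc
}

#' Scan sequences with a PWM on both strands
#'
#' Slides the PWM over each sequence and its reverse complement and
#' reports every window whose log2-odds score reaches the threshold.
#' Reverse-strand hits are reported at the forward-strand coordinate of
#' the window start. Offsets are relative to the sequence centre.
#' Sequences shorter than the motif yield no hits. \code{N} bases score 0.
#'
#' @param sequences named character vector of DNA sequences
#'   (region id -> sequence over A, C, G, T, N).
#' @param pwm a \code{\linkS4class{Pwm}}.
#' @return data.frame: \code{region_id}, \code{position} (1-based window
#'   start on the forward strand), \code{offset} (signed bp of the window
#'   start relative to the sequence centre), \code{strand}, \code{score}.
#' @export
#' @examples
#' hits <- scanPwm(c(r1 = "AAAATGACTCAAAAA"), defaultAP1Pwm())
#' hits
scanPwm <- function(sequences, pwm) {
  stopifnot(is(pwm, "Pwm"))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  bad <- grepl("[^ACGTNacgtn]", sequences)
  if (any(bad))
    stop("sequences contain letters outside {A,C,G,T,N}: ",
         paste(head(names(sequences)[bad], 5), collapse = ", "))
  L <- ncol(pwm@logOdds)
  res <- lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    w <- nchar(s)
    if (w < L) return(NULL)
    enc <- encodeDNA(s)
    centre <- w / 2
    fwd <- windowScores(enc, pwm@logOdds)
    rcEnc <- rev(ifelse(enc == 0L, 0L, 5L - enc))
    rev <- windowScores(rcEnc, pwm@logOdds)
    # window starting at i on the reverse strand covers forward positions
    # (w - L - i + 2) .. (w - i + 1); report its forward start
    hitF <- which(fwd >= pwm@threshold)
    hitR <- which(rev >= pwm@threshold)
    if (!length(hitF) && !length(hitR)) return(NULL)
    posR <- w - L - hitR + 2L
    data.frame(
      region_id = id,
      position = c(hitF, posR),
      offset = c(hitF, posR) - 1L + (L / 2) - centre,
      strand = rep(c("+", "-"), c(length(hitF), length(hitR))),
      score = c(fwd[hitF], rev[hitR]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(region_id = character(), position = integer(),
                      offset = numeric(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binomial motif enrichment in target versus background regions
#'
#' Computes the fraction of target and background regions containing at
#' least one PWM hit and the upper-tail binomial p-value of the target
#' hit count given the background hit fraction as success probability.
#' When the background fraction is zero but targets have hits, a floor
#' rate of \eqn{1/(2 n_{background})} is used.
#'
#' @param targetSequences named character vector of target region
#'   sequences.
#' @param backgroundSequences named character vector of background region
#'   sequences (non-empty).
#' @param pwm a \code{\linkS4class{Pwm}}.
#' @return list: \code{targetFraction}, \code{backgroundFraction},
#'   \code{nTarget}, \code{nBackground}, \code{pvalue}.
#' @export
motifEnrichment <- function(targetSequences, backgroundSequences, pwm) {
  if (!length(targetSequences)) stop("target set is empty")
  if (!length(backgroundSequences)) stop("background set is empty")
  hitIds <- function(seqs) unique(scanPwm(seqs, pwm)$region_id)
  kT <- sum(names(targetSequences) %in% hitIds(targetSequences))
  kB <- sum(names(backgroundSequences) %in% hitIds(backgroundSequences))
  nT <- length(targetSequences); nB <- length(backgroundSequences)
  rate <- kB / nB
  if (rate == 0 && kT > 0) rate <- 1 / (2 * nB)
  p <- pbinom(kT - 1, nT, rate, lower.tail = FALSE)
  list(targetFraction = kT / nT, backgroundFraction = kB / nB,
       nTarget = nT, nBackground = nB, pvalue = p)
}

#' Histogram of motif hit offsets relative to the region centre
#'
#' @param hits data.frame from \code{\link{scanPwm}}.
#' @param binWidth bin width in bp (> 0).
#' @return data.frame: \code{binStart}, \code{binEnd} (signed offsets,
#'   symmetric about 0), \code{count}.
#' @export
centerProfile <- function(hits, binWidth = 10) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (!nrow(hits))
    return(data.frame(binStart = numeric(), binEnd = numeric(),
                      count = integer()))
  lim <- max(abs(hits$offset), binWidth)
  nbin <- ceiling(lim / binWidth)
  breaks <- seq(-nbin * binWidth, nbin * binWidth, by = binWidth)
  ct <- table(cut(hits$offset, breaks, include.lowest = TRUE,
                  right = FALSE))
  data.frame(binStart = breaks[-length(breaks)], binEnd = breaks[-1],
             count = as.integer(ct), row.names = NULL)
}
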