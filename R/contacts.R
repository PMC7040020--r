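#' Fit a distance-decay background model for promoter contacts
#'
#' Models the expected pooled count of a cis contact as a power law in
#' genomic distance times multiplicative bait and other-end bias factors:
#' \deqn{\log \mu = \beta_0 - \alpha \log d + \log b_{bait} + \log b_{oe}.}
#' The decay exponent and intercept are fitted by a Poisson log-linear
#' regression on per-contact mean counts, alternating with row/column
#' rescaling of the bias factors (observed over fitted totals per bait and
#' per other end, recentred to geometric mean 1). The NB dispersion of the
#' per-sample counts around the fitted means is estimated by the method of
#' moments. Trans contacts (distance \code{NA}) are excluded from the
#' decay fit and later scored against a constant background rate equal to
#' their global mean count.
#'
#' Because genuine interactions sit far above the decay background, the
#' fit is made robust by excluding contacts whose observed mean exceeds
#' \code{trimRatio} times the current fit from the regression and bias
#' updates; otherwise enriched contacts would inflate the background and
#' mask themselves.
#'
#' @param contacts a \code{\linkS4class{ContactSet}}.
#' @param nIter number of bias/decay alternations.
#' @param trimRatio observed/fitted ratio above which a contact is
#'   treated as signal and excluded from the background estimation.
#' @return list of class \code{contactBackground}: \code{alpha},
#'   \code{intercept} (log expected mean count at 1 bp for unit biases),
#'   \code{baitBias}, \code{oeBias} (named vectors), \code{dispersion},
#'   \code{transRate}, and the fitted per-contact expected mean
#'   \code{expected} (per sample at size factor 1, named by contact id).
#' @export
fitContactBackground <- function(contacts, nIter = 10L, trimRatio = 3) {
  stopifnot(is(contacts, "ContactSet"))
  k <- assay(contacts, "counts")
  d <- contactDistance(contacts)
  cis <- !is.na(d)
  if (sum(cis) < 500L)
    stop("at least 500 cis contacts are required to fit the background")
  dc <- d[cis]
  if (diff(range(log10(dc))) < 1)
    stop("degenerate distance range: cis contacts must span at least one decade")
  m <- rowMeans(k)[cis]
  bait <- baitFrags(contacts)[cis]
  oe <- otherEndFrags(contacts)[cis]
  ld <- log(dc)

  baitBias <- setNames(rep(1, length(unique(bait))), unique(bait))
  oeBias <- setNames(rep(1, length(unique(oe))), unique(oe))
  # robust initial decay fit on the log scale (geometric-mean-like, so a
  # minority of strongly enriched contacts cannot drag the intercept up),
  # then flag likely interactions before any parameter sees them
  ls0 <- stats::lm(log(m + 0.5) ~ ld)
  mu <- exp(unname(coef(ls0)[1]) + unname(coef(ls0)[2]) * ld)
  use <- m < trimRatio * mu
  alpha <- NA_real_; intercept <- NA_real_
  # phase 1: converge the trimmed decay fit with neutral biases, so that
  # enriched contacts are fully flagged before any bias is estimated;
  # phase 2 (last 3 iterations): alternate bias updates with refitting
  for (it in seq_len(nIter)) {
    offs <- log(baitBias[bait]) + log(oeBias[oe])
    fit <- glm(m[use] ~ ld[use], family = stats::quasipoisson(link = "log"),
               offset = offs[use])
    alpha <- -unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    mu <- exp(intercept - alpha * ld + offs)
    use <- m < trimRatio * mu
    if (it <= nIter - 3L) next
    # smoothed observed/fitted ratios; a bias is only identifiable for a
    # fragment backed by several background contacts, so fragments with
    # fewer than 3 usable contacts keep a neutral bias of 1
    nb <- table(bait[use]); no <- table(oe[use])
    rb <- (tapply(m[use], bait[use], sum) + 0.5) /
      (tapply(mu[use], bait[use], sum) + 0.5)
    rb <- rb[names(rb) %in% names(nb)[nb >= 3L]]
    baitBias[names(rb)] <- baitBias[names(rb)] * rb
    baitBias <- baitBias / exp(mean(log(baitBias)))
    mu <- exp(intercept - alpha * ld + log(baitBias[bait]) + log(oeBias[oe]))
    ro <- (tapply(m[use], oe[use], sum) + 0.5) /
      (tapply(mu[use], oe[use], sum) + 0.5)
    ro <- ro[names(ro) %in% names(no)[no >= 3L]]
    oeBias[names(ro)] <- oeBias[names(ro)] * ro
    oeBias <- oeBias / exp(mean(log(oeBias)))
  }
  expected <- exp(intercept - alpha * ld + log(baitBias[bait]) +
                    log(oeBias[oe]))

  # method-of-moments dispersion on per-sample counts around expected
  kc <- k[cis, , drop = FALSE]
  v <- rowVarsBase(kc)
  mrow <- rowMeans(kc)
  phiHat <- (v - mrow) / pmax(expected^2, 1e-8)
  dispersion <- max(median(phiHat[use & expected > 5], na.rm = TRUE), 1e-4)

  expAll <- rep(NA_real_, length(d))
  expAll[cis] <- expected
  transRate <- if (any(!cis)) mean(rowMeans(k[!cis, , drop = FALSE]))
    else NA_real_
  expAll[!cis] <- transRate
  names(expAll) <- rowData(contacts)$contact_id
  structure(list(alpha = alpha, intercept = intercept,
                 baitBias = baitBias, oeBias = oeBias,
                 dispersion = dispersion, transRate = transRate,
                 expected = expAll),
            class = "contactBackground")
}

#' @export
print.contactBackground <- function(x, ...) {
  cat("contactBackground: alpha =", round(x$alpha, 3),
      "| dispersion =", signif(x$dispersion, 3),
      "|", length(x$baitBias), "bait biases\n")
  invisible(x)
}

#' Score contacts against the background, per condition
#'
#' Pools counts across replicates within each condition and computes the
#' upper-tail negative-binomial p-value of the pooled observed count
#' against the background expectation; the score is \eqn{-\log_{10} p} and
#' a contact is a valid interaction in a condition when its score exceeds
#' \code{validityThreshold} (default 5). The pooled NB variance accounts
#' for the per-sample dispersion of the background model.
#'
#' @param contacts a \code{\linkS4class{ContactSet}}.
#' @param background a \code{contactBackground} fitted on the same table.
#' @param validityThreshold score above which a contact is valid.
#' @return data.frame: \code{contact_id}, \code{condition},
#'   \code{observed}, \code{expected}, \code{score}, \code{valid}; one row
#'   per contact and condition.
#' @export
scoreContacts <- function(contacts, background, validityThreshold = 5) {
  stopifnot(is(contacts, "ContactSet"))
  ids <- rowData(contacts)$contact_id
  miss <- setdiff(ids, names(background$expected))
  if (length(miss))
    stop("contact(s) absent from background domain: ",
         paste(head(miss, 5), collapse = ", "))
  k <- assay(contacts, "counts")
  cond <- as.character(colData(contacts)$condition)
  mu1 <- background$expected[ids]
  phi <- background$dispersion
  out <- lapply(unique(cond), function(cc) {
    sel <- cond == cc
    n <- sum(sel)
    obs <- rowSums(k[, sel, drop = FALSE])
    E <- mu1 * n
    varSum <- E + phi * mu1^2 * n     # sum of n independent NB draws
    sizeEff <- ifelse(varSum > E, E^2 / (varSum - E), Inf)
    p <- ifelse(is.finite(sizeEff),
                pnbinom(obs - 1, mu = E, size = sizeEff,
                        lower.tail = FALSE),
                stats::ppois(obs - 1, E, lower.tail = FALSE))
    score <- -log10(pmax(p, 1e-300))
    data.frame(contact_id = ids, condition = cc, observed = obs,
               expected = E, score = score,
               valid = score > validityThreshold,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Differential contact calling
#'
#' Restricts to contacts whose mean raw count exceeds \code{minMean} in
#' EACH condition, then applies the moderated NB Wald test with BH
#' correction (over the filtered set only) at \code{fdr} (default 0.1).
#' All surviving contacts with \code{padj < fdr} are reported as altered
#' regardless of fold change; the >2-fold subset is flagged separately.
#'
#' @param contacts a \code{\linkS4class{ContactSet}}.
#' @param reference reference condition label.
#' @param minMean mean-count filter per condition (default 10).
#' @param fdr FDR threshold (default 0.1).
#' @return list: \code{results} (per tested contact: Wald columns plus
#'   \code{altered} and \code{fold2}), \code{nFiltered} (contacts removed
#'   by the mean filter), \code{alteredIds}, \code{fold2Ids}.
#' @export
differentialContacts <- function(contacts, reference = NULL, minMean = 10,
                                 fdr = 0.1) {
  stopifnot(is(contacts, "ContactSet"))
  k <- assay(contacts, "counts")
  cond <- as.character(colData(contacts)$condition)
  lev <- conditionLevels(cond, reference)
  mA <- rowMeans(k[, cond == lev[1], drop = FALSE])
  mB <- rowMeans(k[, cond == lev[2], drop = FALSE])
  keep <- mA > minMean & mB > minMean
  ids <- rowData(contacts)$contact_id
  res <- nbWaldTest(k[keep, , drop = FALSE], cond, reference = lev[1])
  res$feature_id <- ids[keep]
  res$altered <- !is.na(res$padj) & res$padj < fdr
  res$fold2 <- res$altered & abs(res$log2FC) > 1
  list(results = res, nFiltered = sum(!keep),
       alteredIds = res$feature_id[res$altered],
       fold2Ids = res$feature_id[res$fold2])
}
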