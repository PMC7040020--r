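# Internal helpers shared across modules.

# Deterministic sub-seed for a named random substream. Keeps every assay on
# its own stream so adding one assay never perturbs another, and stays below
# .Machine$integer.max.
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) + 7919 * h) %% 2147483646L + 1L)
}

rowVarsBase <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# log-uniform draw on [lo, hi]
rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# Accept either a count matrix + condition vector or a SummarizedExperiment
# whose colData carries 'condition'. Returns list(counts, condition).
resolveCounts <- function(counts, condition = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    cd <- colData(counts)
    if (is.null(condition)) {
      if (!"condition" %in% colnames(cd))
        stop("SummarizedExperiment colData must contain a 'condition' column")
      condition <- as.character(cd$condition)
    }
    counts <- assay(counts)
  }
  counts <- as.matrix(counts)
  if (is.null(condition))
    stop("a 'condition' vector is required when counts is a plain matrix")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("length(condition) must equal ncol(counts)")
  if (length(unique(condition)) != 2L)
    stop("exactly two condition levels are required")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  list(counts = counts, condition = condition)
}

# Order the two condition labels: reference first. If a reference level is
# given use it, otherwise first occurrence order.
conditionLevels <- function(condition, reference = NULL) {
  lev <- unique(condition)
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference level '", reference,
                                  "' not present in condition labels")
    lev <- c(reference, setdiff(lev, reference))
  }
  lev
}
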