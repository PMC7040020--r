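#' Coordinate convention converters
#'
#' Genomic intervals are held in memory in the 1-based closed convention
#' of \code{GRanges}; BED-family files on disk are 0-based half-open.
#' These converters are exact inverses of each other.
#'
#' @param start,end interval coordinates.
#' @return a data.frame with converted \code{start} and \code{end}.
#' @export
#' @examples
#' zeroToOneBased(0, 100)  # 1..100
#' oneToZeroBased(1, 100)  # 0..100
zeroToOneBased <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname zeroToOneBased
#' @export
oneToZeroBased <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' Read and write BED region files
#'
#' BED3+ dialect: tab-separated, 0-based half-open, optional columns 4
#' (name, used as \code{region_id}) and 5 (score). \code{track} and
#' \code{browser} header lines and \code{#} comments are skipped.
#' Malformed lines (wrong column count, non-numeric or negative
#' coordinates, start >= end) raise an error naming the line number.
#'
#' @param path file path.
#' @return \code{readBed}: a \code{GRanges} with \code{region_id}.
#' @export
readBed <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(raw)
  lineNo <- which(keep)
  if (!length(lineNo)) stop("no data lines in ", path)
  parts <- strsplit(raw[lineNo], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", lineNo[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  st <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  en <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(st) | is.na(en) | st < 0 | en <= st)
  if (length(bad))
    stop("malformed BED line ", lineNo[bad[1]],
         ": start/end must be numeric with 0 <= start < end")
  name <- ifelse(nf >= 4L, vapply(parts, function(p)
    if (length(p) >= 4L) p[[4L]] else NA_character_, ""), NA_character_)
  conv <- zeroToOneBased(as.integer(st), as.integer(en))
  gr <- GRanges(chrom, IRanges(conv$start, conv$end))
  mcols(gr)$region_id <- ifelse(is.na(name),
                                sprintf("region%05d", seq_along(gr)), name)
  names(gr) <- mcols(gr)$region_id
  gr
}

#' @rdname readBed
#' @param regions a \code{GRanges} (a \code{region_id} column is written
#'   as the BED name field).
#' @export
writeBed <- function(regions, path) {
  conv <- oneToZeroBased(start(regions), end(regions))
  name <- if ("region_id" %in% colnames(mcols(regions)))
    mcols(regions)$region_id
  else if ("frag_id" %in% colnames(mcols(regions)))
    mcols(regions)$frag_id
  else sprintf("region%05d", seq_along(regions))
  df <- data.frame(as.character(seqnames(regions)), conv$start, conv$end,
                   name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write contact tables
#'
#' BEDPE-extended TSV with a header: columns \code{contact_id},
#' \code{bait_frag_id}, \code{otherend_frag_id}, \code{distance}, then
#' one count column per sample (named by sample id). The sample sheet
#' supplies the condition of each count column; a mismatch between count
#' columns and sample sheet is an error, as are negative counts.
#'
#' @param path file path.
#' @param samples sample sheet data.frame with \code{sample_id} and
#'   \code{condition} (see \code{\link{readSampleSheet}}).
#' @return \code{readContacts}: a \code{\linkS4class{ContactSet}}.
#' @export
readContacts <- function(path, samples) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("contact_id", "bait_frag_id", "otherend_frag_id", "distance")
  if (!all(fixed %in% colnames(df)))
    stop("contact file must contain columns: ",
         paste(fixed, collapse = ", "))
  countCols <- setdiff(colnames(df), fixed)
  if (!setequal(countCols, samples$sample_id))
    stop("count columns do not match the sample sheet: file has ",
         paste(countCols, collapse = ","), " vs sheet ",
         paste(samples$sample_id, collapse = ","))
  k <- as.matrix(df[, samples$sample_id, drop = FALSE])
  if (any(k < 0)) stop("negative counts in ", path)
  contactSet(k, df$bait_frag_id, df$otherend_frag_id,
             ifelse(is.na(df$distance), NA_real_, df$distance),
             condition = samples$condition,
             replicate = samples$replicate,
             contactId = df$contact_id)
}

#' @rdname readContacts
#' @param contacts a \code{\linkS4class{ContactSet}}.
#' @export
writeContacts <- function(contacts, path) {
  rd <- as.data.frame(rowData(contacts))
  k <- assay(contacts, "counts")
  df <- cbind(rd[, c("contact_id", "bait_frag_id", "otherend_frag_id",
                     "distance")], as.data.frame(k))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write count matrices with a sample sheet
#'
#' Count matrices are TSV with a header of sample ids and feature ids in
#' the first column; the sample sheet is a TSV with columns
#' \code{sample_id}, \code{condition}, \code{replicate}.
#'
#' @param path file path.
#' @return \code{readCountMatrix}: integer matrix with feature rownames.
#' @export
readCountMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname readCountMatrix
#' @param counts matrix (or \code{SummarizedExperiment}) to write.
#' @export
writeCountMatrix <- function(counts, path) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readCountMatrix
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must contain: ", paste(need, collapse = ", "))
  df
}

#' @rdname readCountMatrix
#' @param samples sample sheet data.frame.
#' @export
writeSampleSheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
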