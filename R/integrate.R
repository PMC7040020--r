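#' Assign regions to restriction fragments
#'
#' Maps every region to each restriction fragment it overlaps by at least
#' 1 bp. Because the fragments partition the genome, every region on a
#' known chromosome maps to at least one fragment; a region spanning a
#' fragment boundary maps to all fragments it touches.
#'
#' @param regions \code{GRanges} with a \code{region_id} column.
#' @param genome a \code{\linkS4class{GenomeModel}}.
#' @return data.frame: \code{region_id}, \code{frag_id}, \code{overlap}
#'   (bp of overlap).
#' @export
assignToFragments <- function(regions, genome) {
  unknown <- setdiff(unique(as.character(seqnames(regions))),
                     names(genome@chromLengths))
  if (length(unknown))
    stop("region(s) on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  fr <- fragments(genome)
  ov <- findOverlaps(regions, fr)
  qh <- queryHits(ov); sh <- subjectHits(ov)
  overlap <- pmin(end(regions)[qh], end(fr)[sh]) -
    pmax(start(regions)[qh], start(fr)[sh]) + 1L
  rid <- if ("region_id" %in% colnames(mcols(regions)))
    mcols(regions)$region_id else as.character(qh)
  data.frame(region_id = rid[qh],
             frag_id = mcols(fr)$frag_id[sh],
             overlap = overlap, stringsAsFactors = FALSE)
}

# fragment-level acetylation summary: a fragment is differential when any
# assigned region is; its log2FC is that of the largest-|log2FC|
# differential region (or largest-|log2FC| region overall when none is).
fragmentDiffSummary <- function(assignment, regionDiff) {
  d <- merge(assignment, regionDiff, by.x = "region_id",
             by.y = "feature_id")
  if (!nrow(d))
    return(data.frame(frag_id = character(), log2FC = numeric(),
                      differential = logical()))
  d$differential <- d$call != "unchanged"
  ord <- order(d$frag_id, -d$differential, -abs(d$log2FC))
  d <- d[ord, ]
  top <- d[!duplicated(d$frag_id), ]
  data.frame(frag_id = top$frag_id, log2FC = top$log2FC,
             differential = top$differential,
             region_id = top$region_id, stringsAsFactors = FALSE)
}

#' Link enhancers to genes through valid promoter contacts
#'
#' A link is created for every (gene, enhancer fragment) pair such that a
#' contact between the gene's bait fragment and the enhancer fragment is a
#' valid interaction (score above threshold) in at least one condition,
#' and at least one enhancer region is assigned to the other-end fragment.
#' A bait serving several genes yields one link per gene.
#'
#' @param contacts a \code{\linkS4class{ContactSet}}.
#' @param scores per-condition scores from \code{\link{scoreContacts}}.
#' @param enhancerAssignment data.frame from
#'   \code{\link{assignToFragments}} restricted to enhancer regions.
#' @param geneBaits data.frame with \code{gene_id} and
#'   \code{bait_frag_id} (see \code{\link{baitMap}}).
#' @return data.frame, one row per (gene, enhancer fragment, region):
#'   ids, per-condition scores \code{score_ref}/\code{score_alt},
#'   validity flags and \code{contact_id}.
#' @export
linkEnhancersToGenes <- function(contacts, scores, enhancerAssignment,
                                 geneBaits) {
  rd <- as.data.frame(rowData(contacts))
  conds <- unique(scores$condition)
  sw <- data.frame(contact_id = scores$contact_id[scores$condition == conds[1]],
                   score_ref = scores$score[scores$condition == conds[1]])
  s2 <- data.frame(contact_id = scores$contact_id[scores$condition == conds[2]],
                   score_alt = scores$score[scores$condition == conds[2]],
                   valid_alt = scores$valid[scores$condition == conds[2]])
  sw$valid_ref <- scores$valid[scores$condition == conds[1]]
  tab <- merge(merge(rd, sw, by = "contact_id"), s2, by = "contact_id")
  tab <- tab[tab$valid_ref | tab$valid_alt, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(gene_id = character(), bait_frag_id = character(),
                      enhancer_frag_id = character(),
                      region_id = character(), contact_id = character(),
                      score_ref = numeric(), score_alt = numeric(),
                      valid_ref = logical(), valid_alt = logical(),
                      stringsAsFactors = FALSE))
  tab <- merge(tab, geneBaits, by = "bait_frag_id")
  enh <- enhancerAssignment[, c("region_id", "frag_id")]
  names(enh)[2] <- "otherend_frag_id"
  tab <- merge(tab, enh, by = "otherend_frag_id")
  out <- data.frame(gene_id = tab$gene_id,
                    bait_frag_id = tab$bait_frag_id,
                    enhancer_frag_id = tab$otherend_frag_id,
                    region_id = tab$region_id,
                    contact_id = tab$contact_id,
                    score_ref = tab$score_ref, score_alt = tab$score_alt,
                    valid_ref = tab$valid_ref, valid_alt = tab$valid_alt,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$enhancer_frag_id, out$region_id), ,
      drop = FALSE]
}

#' Classify linked enhancer fragments into CRE classes
#'
#' Each linked enhancer fragment is classified by the combination of its
#' acetylation status (differential vs unchanged, from the H3K27Ac
#' differential call of its assigned regions) and its contact status
#' (altered when ANY of its promoter contacts is altered, stable
#' otherwise): class i = stable contact + differential acetylation,
#' class ii = altered contact + unchanged acetylation, class iii = altered
#' contact + differential acetylation, and unmodified otherwise.
#'
#' @param links data.frame from \code{\link{linkEnhancersToGenes}}.
#' @param acetylationDiff classified H3K27Ac results (the \code{results}
#'   element of \code{\link{differentialRegions}}).
#' @param contactDiff result of \code{\link{differentialContacts}}.
#' @param enhancerAssignment data.frame from
#'   \code{\link{assignToFragments}}.
#' @return data.frame, one row per linked enhancer fragment:
#'   \code{enhancer_frag_id}, \code{acetylation} (differential/unchanged),
#'   \code{contact} (altered/stable), \code{cre_class} (i/ii/iii/
#'   unmodified), \code{log2FC} (acetylation).
#' @export
classifyCREs <- function(links, acetylationDiff, contactDiff,
                         enhancerAssignment) {
  fragIds <- unique(links$enhancer_frag_id)
  fs <- fragmentDiffSummary(
    enhancerAssignment[enhancerAssignment$frag_id %in% fragIds, ,
                       drop = FALSE],
    acetylationDiff)
  missing <- setdiff(fragIds, fs$frag_id)
  if (length(missing))
    stop("no acetylation differential entry for fragment(s): ",
         paste(head(missing, 5), collapse = ", "))
  altered <- unique(links$contact_id[
    links$contact_id %in% contactDiff$alteredIds])
  fragAltered <- tapply(links$contact_id %in% altered,
                        links$enhancer_frag_id, any)
  fs <- fs[match(fragIds, fs$frag_id), ]
  acet <- ifelse(fs$differential, "differential", "unchanged")
  cont <- ifelse(fragAltered[fragIds], "altered", "stable")
  cls <- ifelse(cont == "stable" & acet == "differential", "i",
         ifelse(cont == "altered" & acet == "unchanged", "ii",
         ifelse(cont == "altered" & acet == "differential", "iii",
                "unmodified")))
  data.frame(enhancer_frag_id = fragIds, acetylation = acet,
             contact = cont, cre_class = cls, log2FC = fs$log2FC,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect differential enhancer usage
#'
#' A gene shows differential enhancer usage when, among its linked
#' enhancer fragments, at least one is differentially acetylated with a
#' positive log2 fold change and at least one with a negative one (a gain
#' at one enhancer concomitant with a loss at another enhancer of the same
#' gene). Events are reported with both enhancer sets and stratified by
#' whether any involved enhancer has an altered contact.
#'
#' @param links data.frame from \code{\link{linkEnhancersToGenes}}.
#' @param acetylationDiff classified H3K27Ac results (with \code{call}).
#' @param enhancerAssignment data.frame from
#'   \code{\link{assignToFragments}}.
#' @param creRecords optional result of \code{\link{classifyCREs}} used
#'   for the contact-status stratification.
#' @return list: \code{events} (per gene: up/down enhancer fragment ids,
#'   \code{anyAlteredContact}), \code{nGenes}, \code{nEnhancers}.
#' @export
detectDifferentialUsage <- function(links, acetylationDiff,
                                    enhancerAssignment,
                                    creRecords = NULL) {
  fs <- fragmentDiffSummary(
    enhancerAssignment[enhancerAssignment$frag_id %in%
                         links$enhancer_frag_id, , drop = FALSE],
    acetylationDiff)
  lk <- unique(links[, c("gene_id", "enhancer_frag_id")])
  lk <- merge(lk, fs, by.x = "enhancer_frag_id", by.y = "frag_id")
  lk <- lk[lk$differential, , drop = FALSE]
  events <- list()
  for (g in unique(lk$gene_id)) {
    sub <- lk[lk$gene_id == g, ]
    up <- sub$enhancer_frag_id[sub$log2FC > 0]
    dn <- sub$enhancer_frag_id[sub$log2FC < 0]
    if (length(up) && length(dn)) {
      anyAlt <- if (!is.null(creRecords))
        any(creRecords$contact[match(c(up, dn),
                                     creRecords$enhancer_frag_id)] ==
              "altered", na.rm = TRUE) else NA
      events[[g]] <- list(gene_id = g, up = up, down = dn,
                          anyAlteredContact = anyAlt)
    }
  }
  nEnh <- if (length(events))
    length(unique(unlist(lapply(events, function(e) c(e$up, e$down)))))
    else 0L
  list(events = unname(events), nGenes = length(events),
       nEnhancers = nEnh)
}

#' Integrate transcription-factor occupancy with acetylation and expression
#'
#' Joins, per enhancer fragment, the H3K27Ac log2 fold change with each
#' occupancy factor's log2 fold change (fragment-level summaries via
#' \code{\link{assignToFragments}}) and with the expression change of
#' linked genes. Reports the Pearson correlation between each factor's
#' fold changes and the acetylation fold changes at shared fragments, and
#' the number of enhancer fragments with differential factor occupancy
#' linked to differentially expressed genes.
#'
#' @param links data.frame from \code{\link{linkEnhancersToGenes}}.
#' @param acetylationDiff classified H3K27Ac results.
#' @param tfDiffs named list: factor name -> classified results over that
#'   factor's regions.
#' @param tfAssignments named list: factor name -> region-to-fragment
#'   assignment (\code{\link{assignToFragments}}).
#' @param expressionDiff classified expression results (gene level).
#' @param enhancerAssignment H3K27Ac region-to-fragment assignment.
#' @return list: \code{table} (per enhancer fragment: acetylation and
#'   factor log2FCs), \code{correlations} (named vector per factor),
#'   \code{diffTfEnhancersLinkedToDE} (named vector per factor),
#'   \code{nDeGenesWithDiffTf}.
#' @export
integrateTF <- function(links, acetylationDiff, tfDiffs, tfAssignments,
                        expressionDiff, enhancerAssignment) {
  acet <- fragmentDiffSummary(enhancerAssignment, acetylationDiff)
  tab <- data.frame(frag_id = acet$frag_id, acet_log2FC = acet$log2FC,
                    acet_differential = acet$differential,
                    stringsAsFactors = FALSE)
  cors <- numeric(0)
  linkedDE <- integer(0)
  deGenes <- expressionDiff$feature_id[expressionDiff$call != "unchanged"]
  deSet <- character(0)
  for (tf in names(tfDiffs)) {
    fsT <- fragmentDiffSummary(tfAssignments[[tf]], tfDiffs[[tf]])
    idx <- match(tab$frag_id, fsT$frag_id)
    tab[[paste0(tf, "_log2FC")]] <- fsT$log2FC[idx]
    tab[[paste0(tf, "_differential")]] <- fsT$differential[idx]
    shared <- !is.na(idx)
    cors[tf] <- if (sum(shared) > 2)
      cor(tab$acet_log2FC[shared], fsT$log2FC[idx[shared]]) else NA_real_
    diffFrag <- fsT$frag_id[fsT$differential]
    sel <- links$enhancer_frag_id %in% diffFrag &
      links$gene_id %in% deGenes
    linkedDE[tf] <- length(unique(links$enhancer_frag_id[sel]))
    deSet <- union(deSet, unique(links$gene_id[sel]))
  }
  list(table = tab, correlations = cors,
       diffTfEnhancersLinkedToDE = linkedDE,
       nDeGenesWithDiffTf = length(deSet))
}
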