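#' Pipeline configuration
#'
#' Collects every threshold of the integrative analysis in one object.
#' Defaults are the conventional cutoffs of the workflow: expression FDR
#' 0.01 with 2/4-fold tiers, region FDR 0.05 with 2-fold cutoff, contact
#' validity score 5, contact FDR 0.1 with mean-count filter 10, EISA FDR
#' 0.05, and the -1000/+100 bp promoter window. A \code{simulate} block
#' (arguments of \code{\link{simConfig}}) describes the synthetic input.
#'
#' @param yaml optional path to a YAML file whose keys override the
#'   defaults; explicit arguments override the file.
#' @param deFdr,deTiers expression FDR and fold-change tiers.
#' @param peakFdr,peakFc region FDR and fold-change cutoff.
#' @param contactScore contact validity score threshold.
#' @param contactFdr,contactMinMean differential-contact FDR and
#'   mean-count filter.
#' @param eisaFdr,eisaFloor EISA FDR and expression floor.
#' @param promoterWindow,ttsWindow annotation windows (bp around TSS/TES).
#' @param seed master seed.
#' @param outdir output directory (\code{NULL}: no files are written).
#' @param simulate named list of \code{\link{simConfig}} overrides.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(yaml = NULL, deFdr = 0.01, deTiers = c(2, 4),
                           peakFdr = 0.05, peakFc = 2, contactScore = 5,
                           contactFdr = 0.1, contactMinMean = 10,
                           eisaFdr = 0.05, eisaFloor = 8,
                           promoterWindow = c(-1000L, 100L),
                           ttsWindow = c(-100L, 1000L),
                           seed = 1L, outdir = NULL, simulate = list()) {
  cfg <- list(deFdr = deFdr, deTiers = deTiers, peakFdr = peakFdr,
              peakFc = peakFc, contactScore = contactScore,
              contactFdr = contactFdr, contactMinMean = contactMinMean,
              eisaFdr = eisaFdr, eisaFloor = eisaFloor,
              promoterWindow = promoterWindow, ttsWindow = ttsWindow,
              seed = seed, outdir = outdir, simulate = simulate)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    given <- names(as.list(match.call()))[-1]
    for (nm in setdiff(intersect(names(y), names(cfg)), given))
      cfg[[nm]] <- y[[nm]]
  }
  for (nm in c("deFdr", "peakFdr", "contactFdr", "eisaFdr"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop(nm, " must lie in (0, 1)")
  if (cfg$contactScore < 0 || cfg$contactMinMean < 0)
    stop("contactScore and contactMinMean must be nonnegative")
  class(cfg) <- "pipelineConfig"
  cfg
}

sensFdr <- function(called, truth) {
  tp <- length(intersect(called, truth))
  list(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       fdr = if (length(called)) 1 - tp / length(called) else 0,
       nCalled = length(called), nTruth = length(truth))
}

#' Run the full integrative enhancer-architecture pipeline
#'
#' Executes, in order: synthetic data generation, differential expression
#' with fold-change tiers, exon-intron split analysis, differential
#' region calling for every ChIP assay, genomic-category annotation with
#' the category-shift test, contact background fitting, per-condition
#' contact scoring and differential contact calling, restriction-fragment
#' enhancer-gene linking, CRE classification, differential enhancer usage
#' detection, transcription-factor integration, and AP-1 motif
#' enrichment. A fixed seed yields an identical report.
#'
#' When \code{config$outdir} is set, stage outputs (BED/TSV/JSON) and the
#' report JSON are written there.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with the full \code{report} (counts, correlations,
#'   truth-recovery metrics), and the stage objects: \code{sim},
#'   \code{de}, \code{eisa}, \code{peaks}, \code{annotation},
#'   \code{shift}, \code{background}, \code{scores},
#'   \code{contactDiff}, \code{links}, \code{cres}, \code{usage},
#'   \code{tf}, \code{motif}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  simCfg <- stage("simulate",
                  do.call(simConfig, c(config$simulate,
                                       list(seed = config$seed))))
  sim <- stage("simulate", simulateDataset(simCfg))
  ref <- simCfg$conditions[1]

  # ---- differential expression + EISA ---------------------------------
  de <- stage("diffexpr", {
    res <- nbWaldTest(sim$rna$exon, reference = ref)
    classifyDE(res, fdr = config$deFdr, fcTiers = config$deTiers)
  })
  eisa <- stage("eisa", runEisa(sim$rna$exon, sim$rna$intron,
                                reference = ref,
                                eisaFdr = config$eisaFdr,
                                floor = config$eisaFloor))

  # ---- differential regions per assay ---------------------------------
  peaks <- stage("diffpeaks", lapply(sim$chip, function(a)
    differentialRegions(a$counts, reference = ref, fdr = config$peakFdr,
                        fc = config$peakFc)))
  k27regions <- sim$chip$H3K27Ac$regions
  k27diff <- peaks$H3K27Ac$results

  annotation <- stage("annotate", annotateRegions(
    k27regions, sim$genome, config$promoterWindow, config$ttsWindow))
  shift <- stage("shift", {
    diffIds <- k27diff$feature_id[k27diff$call != "unchanged"]
    diffCat <- table(annotation$category[annotation$region_id %in% diffIds])
    bgCat <- table(annotation$category)
    distributionShiftTest(as.numeric(diffCat), as.numeric(bgCat))
  })

  # ---- contacts --------------------------------------------------------
  background <- stage("contacts", fitContactBackground(sim$contacts))
  scores <- stage("contacts", scoreContacts(sim$contacts, background,
                                            config$contactScore))
  contactDiff <- stage("contacts", differentialContacts(
    sim$contacts, reference = ref, minMean = config$contactMinMean,
    fdr = config$contactFdr))

  # ---- integration -----------------------------------------------------
  enhIds <- annotation$region_id[annotation$category != "promoter"]
  enhRegions <- k27regions[mcols(k27regions)$region_id %in% enhIds]
  enhAssign <- stage("integrate", assignToFragments(enhRegions, sim$genome))
  links <- stage("integrate", linkEnhancersToGenes(
    sim$contacts, scores, enhAssign, baitMap(sim$genome)))
  cres <- stage("integrate", classifyCREs(links, k27diff, contactDiff,
                                          enhAssign))
  usage <- stage("integrate", detectDifferentialUsage(
    links, k27diff, enhAssign, cres))
  tfNames <- setdiff(names(sim$chip), "H3K27Ac")
  tfAssign <- lapply(tfNames, function(tf)
    assignToFragments(sim$chip[[tf]]$regions, sim$genome))
  names(tfAssign) <- tfNames
  tf <- stage("integrate", integrateTF(
    links, k27diff, lapply(peaks[tfNames], `[[`, "results"), tfAssign,
    de$results, enhAssign))

  # ---- motifs ----------------------------------------------------------
  motif <- stage("motifs", {
    diffIds <- k27diff$feature_id[k27diff$call != "unchanged"]
    target <- sim$sequences[names(sim$sequences) %in% diffIds]
    bg <- sim$sequences[!names(sim$sequences) %in% diffIds]
    ap1 <- defaultAP1Pwm()
    if (length(target) && length(bg)) {
      enr <- motifEnrichment(target, bg, ap1)
      prof <- centerProfile(scanPwm(target, ap1), binWidth = 10)
    } else {  # nothing differential: no enrichment to compute
      enr <- list(targetFraction = NA_real_,
                  backgroundFraction = NA_real_,
                  nTarget = length(target), nBackground = length(bg),
                  pvalue = NA_real_)
      prof <- centerProfile(data.frame(offset = numeric()), 10)
    }
    list(enrichment = enr, profile = prof)
  })

  # ---- truth recovery --------------------------------------------------
  truth <- sim$truth
  gt <- truth@genes
  rt <- truth@regions[truth@regions$assay == "H3K27Ac", ]
  ct <- truth@contacts
  exonTruth <- gt$gene_id[gt$deDirection != 0 | gt$postTxn]
  recovery <- list(
    deGenes = sensFdr(
      de$results$feature_id[!is.na(de$results$padj) &
                              de$results$padj < config$deFdr], exonTruth),
    postTxnGenes = sensFdr(
      eisa$results$gene_id[eisa$results$postTxn],
      gt$gene_id[gt$postTxn]),
    diffEnhancers = sensFdr(
      k27diff$feature_id[k27diff$call != "unchanged"],
      rt$region_id[rt$differential]),
    alteredContacts = sensFdr(contactDiff$alteredIds,
                              ct$contact_id[ct$altered]),
    usageGenes = sensFdr(
      vapply(usage$events, `[[`, "", "gene_id"),
      gt$gene_id[gt$usage]))

  report <- list(
    thresholds = config[c("deFdr", "deTiers", "peakFdr", "peakFc",
                          "contactScore", "contactFdr", "contactMinMean",
                          "eisaFdr", "eisaFloor", "promoterWindow",
                          "ttsWindow", "seed")],
    nGenes = nrow(gt),
    de = list(tierCounts = as.list(de$tierCounts),
              nTested = sum(!is.na(de$results$pvalue))),
    eisa = list(nPostTxn = sum(eisa$results$postTxn),
                correlation = eisa$correlation,
                nFiltered = eisa$nFiltered),
    peaks = lapply(peaks, function(p) as.list(p$tierCounts)),
    categoryShift = shift[c("statistic", "df", "pvalue")],
    contacts = list(
      alphaHat = background$alpha,
      dispersion = background$dispersion,
      nContacts = nrow(rowData(sim$contacts)),
      nValid = length(unique(scores$contact_id[scores$valid])),
      nAltered = length(contactDiff$alteredIds),
      nAlteredFold2 = length(contactDiff$fold2Ids),
      nFiltered = contactDiff$nFiltered),
    integration = list(
      nLinks = nrow(unique(links[, c("gene_id", "enhancer_frag_id")])),
      creClassCounts = as.list(table(cres$cre_class)),
      usageGenes = usage$nGenes, usageEnhancers = usage$nEnhancers,
      tfCorrelations = as.list(tf$correlations),
      diffTfEnhancersLinkedToDE = as.list(tf$diffTfEnhancersLinkedToDE)),
    motif = list(
      targetFraction = motif$enrichment$targetFraction,
      backgroundFraction = motif$enrichment$backgroundFraction,
      log10p = log10(max(motif$enrichment$pvalue, 1e-300))),
    recovery = recovery)

  out <- list(report = report, sim = sim, de = de, eisa = eisa,
              peaks = peaks, annotation = annotation, shift = shift,
              background = background, scores = scores,
              contactDiff = contactDiff, links = links, cres = cres,
              usage = usage, tf = tf, motif = motif)
  if (!is.null(config$outdir)) writePipelineOutputs(out, config$outdir)
  out
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic (no timestamps), so identical runs produce byte-identical
#' files.
#'
#' @param report the \code{report} element of \code{\link{runPipeline}}.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

writePipelineOutputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  writeBed(out$sim$chip$H3K27Ac$regions, fp("h3k27ac_regions.bed"))
  writeBed(fragments(out$sim$genome), fp("fragments.bed"))
  g <- geneRanges(out$sim$genome)
  write.table(
    data.frame(gene_id = mcols(g)$gene_id,
               chrom = as.character(seqnames(g)), start = start(g),
               end = end(g), strand = as.character(strand(g)),
               tss = unname(tssPositions(out$sim$genome))),
    fp("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(genes = truthTable(out$sim$truth, "genes"),
         regions = truthTable(out$sim$truth, "regions"),
         contacts = truthTable(out$sim$truth, "contacts"),
         links = truthTable(out$sim$truth, "links")),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)
  writeSampleSheet(out$sim$samples, fp("samples.tsv"))
  writeCountMatrix(out$sim$rna$exon, fp("exon_counts.tsv"))
  writeCountMatrix(out$sim$rna$intron, fp("intron_counts.tsv"))
  writeContacts(out$sim$contacts, fp("contacts.tsv"))
  write.table(out$de$results, fp("diffexpr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(out$eisa$results, fp("eisa.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(out$links, fp("links.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(out$cres, fp("cre_records.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(out$usage$events, fp("usage_events.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeReport(out$report, fp("report.json"))
  invisible(outdir)
}
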