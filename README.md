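# epiCRE

Integrative analysis of enhancer-architecture changes between two matched
tissue conditions from count-level multi-omic data.

## The problem

In diseases such as uterine leiomyoma, thousands of genes change
expression relative to the matched normal myometrium, yet many
dysregulated promoters show little change in their own chromatin state.
The alternative hypothesis is that the change is encoded distally: at
enhancers whose H3K27 acetylation, transcription-factor occupancy (AP-1,
the CDK8-Mediator submodule) or physical promoter contact strength is
remodelled. Testing that requires joining four count-level assays — exonic
and intronic RNA-seq, region-level ChIP-seq, and promoter capture Hi-C —
on the common coordinate system of the restriction-fragment partition used
by the capture assay.

epiCRE provides this workflow for statisticians and computational
biologists working with matched two-condition designs, together with a
fully specified synthetic-data generator so every stage can be validated
against known truth.

## What it computes

All differential calls share a moderated negative-binomial Wald engine
(counts $K_{ij} \sim \mathrm{NB}(s_j\mu_{gi},\ \phi_i)$, median-of-ratios
size factors, variance-stabilized log2 scale, per-feature variance shrunk
halfway toward a mean–variance trend, BH-FDR):

* **Differential expression** at FDR < 0.01 with nested >2-fold and
  >4-fold tiers (`nbWaldTest`, `classifyDE`).
* **Exon–intron split analysis**: the contrast
  $\Delta_{exon}-\Delta_{intron}$ flags post-transcriptionally regulated
  genes at FDR < 0.05 (`runEisa`).
* **Differential regions** per ChIP assay at FDR < 0.05 and fold change
  > |2|, with five-category genomic annotation (promoter −1000/+100 bp of
  the TSS, tts, exonic, intronic, intergenic) and a $\chi^2$(4) test for a
  shift of differential regions across categories
  (`differentialRegions`, `annotateRegions`, `distributionShiftTest`).
* **Contact scoring** against a robust power-law distance-decay background
  with bait/other-end bias factors,
  $\log\mu = \beta_0 - \alpha\log d + \log b_{bait} + \log b_{oe}$;
  a contact is a valid interaction at score $-\log_{10} p > 5$, and
  differential contacts are called at FDR < 0.1 among contacts with mean
  count > 10 in each condition (`fitContactBackground`, `scoreContacts`,
  `differentialContacts`).
* **Enhancer–promoter linking** through the fragment partition, three-way
  CRE classification (class i: stable contact + differential acetylation;
  class ii: altered contact + unchanged acetylation; class iii: both),
  and **differential enhancer usage** (genes with one gaining and one
  losing linked enhancer) (`linkEnhancersToGenes`, `classifyCREs`,
  `detectDifferentialUsage`, `integrateTF`).
* **PWM motif enrichment** of an AP-1-style TGA(C/G)TCA matrix in
  differential versus unchanged regions, with a peak-centre offset
  profile (`scanPwm`, `motifEnrichment`, `centerProfile`).

## Worked example

```r
library(epiCRE)
out <- runPipeline(pipelineConfig(seed = 1))

unlist(out$report$de$tierCounts)
#> significant       tier2       tier4
#>         275         270         178
```

Of the 1000 simulated genes, 275 are differentially expressed at
FDR < 0.01, 270 of them at >2-fold and 178 at >4-fold (the generator
injected 25% DE genes with |log2FC| between 1.5 and 3, so almost all calls
clear the 2-fold tier).

```r
round(out$report$eisa$correlation, 3)   # 0.883
out$report$eisa$nPostTxn                # 50
```

Exonic and intronic fold changes correlate at 0.88 — the contrast is
predominantly transcriptional — while 50 genes are flagged as
post-transcriptionally regulated (5% were injected with exon-only
changes).

```r
round(out$report$contacts$alphaHat, 3)  # 1.013
out$report$contacts$nValid              # 3008
unlist(out$report$integration$creClassCounts)
#>          i         ii        iii unmodified
#>        687        306         82       1919
out$report$integration$usageGenes       # 105
```

The background fit recovers the simulated decay exponent (truth 1.0);
3008 contacts score as valid interactions. Among linked enhancer
fragments, regions with stable contacts but differential acetylation
(class i) dominate the modified classes, and 105 genes show differential
enhancer usage (100 were designed). The report's `recovery` block scores
every layer against the generator's truth labels — at seed 1, DE genes
are recovered with sensitivity 1.00 at FDR 0.018 and usage genes with
sensitivity 1.00 at FDR 0.048.

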