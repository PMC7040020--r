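Package: epiCRE
Title: Integrative Analysis of Enhancer Architecture from Matched
    Multi-Omic Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting cis-regulatory architecture changes
    between two matched tissue conditions from count-level multi-omic
    data: negative-binomial Wald testing with BH-FDR and fold-change
    tiers, exon-intron split analysis, differential histone-acetylation
    and transcription-factor occupancy regions, promoter capture Hi-C
    contact scoring against a distance-decay background, restriction
    fragment based enhancer-promoter linking, three-class classification
    of modified cis-regulatory elements, differential enhancer usage
    detection, and PWM motif enrichment. A synthetic multi-omic data
    generator with recorded ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR,
    withr,
    optparse,
    knitr
biocViews: Epigenetics, GeneRegulation, DifferentialExpression,
    HiC, ChIPSeq, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'contacts.R'
    'diffcore.R'
    'epiCRE-package.R'
    'genome.R'
    'integrate.R'
    'io.R'
    'motifs.R'
    'peaks.R'
    'pipeline.R'
    'simulate.R'
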