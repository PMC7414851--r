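Package: RepliProfiler
Title: Replication-Timing and Chromatin-Compartment Profiling of
    Replisome-Associated Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-window analysis relating ChIP-seq enrichment of
    replisome-associated factors to replication timing (RT) and Hi-C A/B
    chromatin compartments, together with proximity-ligation-assay (PLA)
    foci-per-nucleus image quantification. Provides 50-kb window binning
    with TPM normalization and log2(ChIP/Input) enrichment, RT and
    eigenvector quantile coverage profiles, A/B compartment eigenvector
    computation from binned Hi-C contact matrices (Knight-Ruiz balancing,
    observed/expected, Pearson correlation, first principal component),
    enriched-window selection with matched random controls and Mann-Whitney
    rank-sum comparisons, nucleus segmentation and size-filtered focus
    detection with parent-child counting, sequential-round rigid image
    registration, and seeded synthetic-data generators for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RepliProfiler-package.R'
    'compartments.R'
    'enrichment.R'
    'pipeline.R'
    'pla.R'
    'simulate.R'
    'utils.R'
    'windows.R'
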