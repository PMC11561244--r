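Package: editdev
Title: Quantification and Differential Analysis of A-to-I RNA Editing
    Across Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for charting adenosine-to-inosine (A-to-I) RNA editing
    across developmental time from aligned RNA-seq reads. Implements
    pileup-based editing-level calling at cataloged sites with read-end,
    splice-proximity, base-quality and SNP masking; the Alu Editing Index
    (AEI) over stranded Alu intervals; pseudobulk aggregation of barcoded
    single-cell or single-nucleus alignments with UMI-based PCR-duplicate
    removal; assembly and harmonization of sites-by-samples editing
    matrices; multiple imputation of missing editing levels by chained
    predictive mean matching; covariate-adjusted per-site linear models
    with empirical-Bayes variance moderation and Benjamini-Hochberg FDR
    control; developmental stage binning with Cohen's d effect sizes; and
    cross-layer summaries linking editing to ADAR-family expression. A
    synthetic-data module generates miniature genomes, annotations,
    stranded Alu repeats, truth tables and SAM alignments with programmed
    editing trajectories so the whole pipeline runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
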