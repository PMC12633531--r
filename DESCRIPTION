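Package: kataegisStorm
Title: Detection, Timing and Attribution of Kataegis in Tumour Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for the analysis of kataegis (focal
    single-base hypermutation) in cancer whole genomes. Detects kataegis
    events from somatic SNVs via exact piecewise-constant-fitting
    segmentation of inter-mutational distances, times events against
    clonal and subclonal tumour evolution using copy number and cancer
    cell fractions, attributes events to APOBEC3A/APOBEC3B through
    accessibility-adjusted TCW/YTCW/RTCW motif enrichment, classifies
    events as structural-variant associated or independent with a
    pseudo-event simulation null on log-spaced distance bins, and runs
    cohort-level statistics (burden regression, driver co-occurrence,
    survival stratification). Ships a fully deterministic synthetic
    cohort generator with planted ground truth so every stage is
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    MASS,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SomaticMutation, WholeGenome, Sequencing, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'detect.R'
    'apobec.R'
    'cohort.R'
    'kataegisStorm-package.R'
    'simulate.R'
    'svproximity.R'
    'timing.R'
    'pipeline.R'
    'utils.R'
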