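Package: methylaging
Title: Aging Methylome Analysis and Epigenetic Clocks for RRBS Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing age-associated DNA methylation from reduced
    representation bisulfite sequencing (RRBS) count tables. Implements the
    full preprocessing chain for Bismark-style coverage files (coverage
    filtering, coverage normalisation, uniting across samples, k-nearest
    neighbour imputation, near-zero-variance removal), per-cytosine
    age-association screening with FDR control, differential methylation
    calling, three epigenetic clock builders (top-k linear, elastic net,
    PCA-based) with serialisation and missing-site prediction, CpG-island
    detection and genomic-context enrichment, position-weight-matrix motif
    scanning with exact score-distribution p-values, the percent-discordant-
    reads (PDR) statistic with a mixed-model age trend, and
    exposure-by-aging interaction analysis along the age-correlation
    continuum. A seeded synthetic-data generator emulates the structure of an
    RRBS aging study (age cohort, exposure cohort, genome, motifs, per-read
    methylation patterns) with known ground truth so the entire pipeline can
    be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    lme4,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    caret,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
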