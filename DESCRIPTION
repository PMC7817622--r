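Package: methedit
Title: Downstream Analysis of Targeted DNA Demethylation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for CRISPR-dCas9-TET1 style targeted DNA
    demethylation experiments. Covers per-read methylation calling from
    bisulfite amplicon sequencing (three-letter alignment, QC filtering,
    pattern maps, read classification), beta-value differential
    methylation on EPIC-like arrays (delta-threshold hypo/hyper sets,
    locus clustering, principal component analysis), exact Fisher-based
    enrichment of CpG subsets in flank-extended genomic windows (binding
    sites, predicted sgRNA off-targets), per-gene enrichment of top
    principal-component loadings with probe-count correction and FDR, and
    intersection of hypo-methylated gene sets with differential-expression
    results. Includes seeded synthetic-data generators with planted ground
    truth for every input so the full pipeline can be exercised and
    validated without access-controlled study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
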