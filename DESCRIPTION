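Package: methylscape
Title: Whole-Genome Bisulfite Differential Methylation Analysis with a
    Closed-Loop Synthetic Methylome Generator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for whole-genome bisulfite sequencing
    (WGBS) differential methylation analysis in plants: per-cytosine
    context classification (CGN/CHG/CHH), chloroplast-based
    non-conversion estimation, weighted methylation levels, window and
    metagene profiles, a root-mean-square permutation test with
    empirical FDR control for differentially methylated site (DMS)
    calling, DMS-to-region (DMR) merging, DMR annotation to genes,
    differentially methylated gene (DMG) and expression (DEG/DEDMG)
    integration, DMR-density peak detection shared across groups,
    methylation-by-feature-density regression, and repeat-proximity
    expression analysis. A fully parameterised synthetic-data module
    generates genomes, annotations, ground-truth methylomes, bisulfite
    count tables and expression matrices with the statistical structure
    the analysis assumes, so every stage can be validated against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    MASS,
    edgeR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
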