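Package: scdrift
Title: Cell-to-Cell Methylation and Transcriptional Heterogeneity in
    Single-Cell Multi-Omics of Ageing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of epigenetic drift in single-cell parallel
    methylome and transcriptome (scM&T-seq) data. Implements a
    cell-to-cell DNA methylation heterogeneity score for genomic regions
    based on pairwise normalised Hamming distance and joint Shannon
    entropy, together with its mean-methylation normalisation (rolling
    median) and sliding-window Z-scored age contrasts; transcriptional
    variability statistics (reads-per-million normalisation, distance to
    the median, expression frequency, cell-cell Spearman correlation
    cohorts, similarity-to-young ranking); a binned-methylation
    epigenetic age clock fitted by penalised regression with
    cell-drop permutation uncertainty; per-cell methylation-expression
    association tests; quality-control filters and coverage-equalising
    down-sampling; and generators of synthetic single-cell methylomes,
    transcriptomes and clock training sets with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
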