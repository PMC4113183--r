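Package: mirDiffReg
Title: Differential Regulation of Small RNAs Across Contrasting Lines After Nerve Injury
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a genome-wide small-RNA-seq
    analysis for finding microRNAs whose injury-induced regulation differs
    between two contrasting rat selection lines. Covers read editing
    (adapter trimming, length filtering, collapsing to unique sequences),
    hierarchical seed-alignment annotation against ordered reference
    libraries with non-templated-addition tolerance, reads-per-million
    normalization with abundance filtering, replicate-pool consistency QC
    by average-linkage clustering with outlier flagging, and the
    SNL-reg / diff-reg regulation statistics with pairwise-estimate
    resampling, Benjamini-Hochberg FDR and permutation nulls. A synthetic
    data module generates count matrices and raw reads with the
    statistical structure the analysis assumes, so every stage is
    testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Sequencing, miRNA, DifferentialExpression, QualityControl, Normalization
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
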