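Package: canidcnv
Title: Windowed Read-Depth Copy-Number Genotyping, Differentiation Scans
    and Copy-Number GWAS for Canid Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning windowed read-depth copy ratios into integer
    copy-number genotypes and downstream population analyses. A Gaussian
    emission hidden Markov model with Baum-Welch trained transitions and
    forward-backward decoding produces per-window posterior copy-number
    calls, which are sharpened by cohort-level Bayes smoothing and 95
    percent credible sets. Deletions are re-genotyped with a fixed-means
    Gaussian mixture. Downstream modules provide subsampled V_ST
    differentiation scans, balanced-basis PCA, copy-number phylogenies with
    indicator-matrix topology comparison, generalized Cochran-Mantel-Haenszel
    and principal-component adjusted regression GWAS on breed-standard
    phenotypes with dual significance thresholds, and annotation
    cross-referencing against Hi-C contacts, CTCF orientation, lncRNA
    tissue labels, conservation scores and leading-SNP blocks. A synthetic
    cohort generator with planted events provides ground truth for
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
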