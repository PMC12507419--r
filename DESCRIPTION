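Package: txclass
Title: Transcriptome State Classification with ANOVA-Ranked Optimal Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Supervised classification of bulk transcriptomes into labeled
    physiological states. Genes are ranked by their one-way ANOVA F-value
    across state categories and an optimal minimal gene set is chosen at the
    elbow of the ranked F-value curve. Samples are projected by classical
    multidimensional scaling, category separation is graded by the mean
    silhouette coefficient, and query transcriptomes are assigned to the
    reference category with the highest mean Spearman correlation. Robustness
    is assessed by leave-one-out cross-validation with stratified reference
    subsampling. Includes a negative-binomial count simulator with planted
    category effects for end-to-end validation, plus Boruta-style
    shadow-feature selection and top-variance selection as baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    limma,
    ranger,
    stats,
    utils,
    withr
Suggests:
    DESeq2,
    mclust,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
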