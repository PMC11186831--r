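Package: divergene
Title: Case/Control Genetic Analysis via Log-Bayes-Factor PCA with
    Permutation Significance and Variant-to-Gene Prioritisation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multivariate case/control genetic association analysis based on
    per-subject, per-variable log Bayes factors (LBFs). Genotype matrices are
    transformed into same-shape LBF matrices contrasting case and control
    genotype models, analysed by eigenvalue-scaled correlation PCA, and
    variable loadings are projected onto the observed case/control direction.
    Significance is assessed by full-pipeline label permutation with Gaussian
    mixture tail p-values, Sidak family-wise and Benjamini-Hochberg
    thresholds. Includes univariate cohort quality control (sex inference,
    missingness, relatedness, exact Hardy-Weinberg test), reference-panel
    co-analysis with Mahalanobis ellipse ancestry selection and sex
    balancing, LD-based SNP-to-gene mapping with weighted-evidence TOPSIS
    prioritisation, drug tractability scoring, protein-protein interaction
    network expansion, and a synthetic cohort generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: GenomeWideAssociationStudies, SNP, PrincipalComponent,
    StatisticalMethod, QualityControl
RoxygenNote: 7.3.3
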