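Package: salivaMarkers
Title: Salivary Proteomics Biomarker Selection by Combined Univariate and
    Multivariate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biomarker-selection pipeline for case/control salivary
    proteomics abundance matrices. Combines per-proteoform differential
    abundance testing (log2 fold change, Wilcoxon rank-sum,
    Benjamini-Hochberg FDR) with a sparse partial least squares
    discriminant analysis (sPLS-DA) classifier coupled to recursive
    feature elimination, merges the two candidate lists with proteoform
    isoform collapsing, prunes a protein-protein interaction network
    (PSI-MI TAB input) down to interactions among the candidates, and
    performs hypergeometric over-representation analysis against GMT
    gene-set collections with affinity-propagation redundancy reduction.
    Includes a synthetic-data generator that emulates the statistical
    structure of a label-free salivary proteome cohort so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
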