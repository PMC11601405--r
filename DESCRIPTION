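Package: twasbiclust
Title: Biclustering of TWAS Gene-Trait Association Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines local, overlapping gene-trait patterns in transcriptome-wide
    association study (TWAS) results. A trait-by-gene matrix of association
    p-values is binarized at a significance threshold, all-ones biclusters are
    enumerated with the BiBit row-pair bit-pattern algorithm, overlapping
    biclusters are grouped into meta-biclusters by gene-set Jaccard similarity
    and average-linkage (UPGMA) clustering, and each meta-bicluster is
    characterized by hypergeometric over-representation analysis of its genes
    and traits against GMT annotation collections. A synthetic-data module
    plants all-ones blocks in uniform-null p-value matrices so every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
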