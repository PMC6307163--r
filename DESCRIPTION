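Package: nvbarcode
Title: Alignment-Free DNA Barcode Analysis with 18-Dimensional Natural Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free representation and taxonomic analysis of DNA
    barcode sequences (e.g. fungal ITS, 500-800 bp). Each sequence is mapped
    to an 18-dimensional natural vector: the count, mean position and
    normalized positional variation of each nucleotide, plus the
    subset-averaged covariance between each pair of nucleotides. On top of
    this representation the package provides convex-hull disjointness tests
    for species point clouds via a feasibility program on convex
    combinations, linear discriminant projections for visualization, random
    forest classification across taxonomic ranks with out-of-bag error
    curves and a macro-averaged one-vs-rest ROC construction, Euclidean
    distance matrices with single-linkage dendrograms and Newick export,
    barcode-gap analysis of intra- versus inter-group distances, and a
    hierarchical synthetic barcode generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    quadprog,
    randomForest,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
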