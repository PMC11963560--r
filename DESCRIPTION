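Package: sparsemeth
Title: Downstream Analysis of Sparse Whole-Genome Bisulfite Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of sparse (invertebrate-style,
    roughly 1-3% CpG) whole-genome bisulfite sequencing methylomes from
    per-cytosine CGmap call tables: coverage and contig filtering, cross-sample
    matrix aggregation with k-nearest-neighbour imputation, strand-symmetry and
    non-conversion quality control against an unmethylated control contig,
    meta-gene, decile, and exon-position methylation profiles, permutation
    tests for age-group differences in methylation, a Lasso leave-one-out
    epigenetic clock, and per-gene age regression. Includes a synthetic-cohort
    generator that emulates the statistical structure of such datasets so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    uwot,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
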