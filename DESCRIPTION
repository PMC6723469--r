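Package: fbpconcord
Title: Annotation Concordance and Copy-Number Analysis for Flavonoid
    Biosynthesis Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing agreement between two genome annotation
    sources for the anthocyanin branch of the flavonoid biosynthesis
    pathway (CHS, CHI, F3H, F3'H, F3'5'H, DFR, ANS).  Mines candidate
    homologs from annotated coding-sequence sets with a relaxed local
    similarity search, classifies cross-source reciprocal best hits as
    perfect, imperfect, or unpaired annotations, rescues unpaired genes
    that co-cluster in codon-aware bootstrap gene trees, and summarises
    concordance, per-species/per-enzyme copy numbers and coding-sequence
    length statistics.  Includes a birth-death gene-family simulator that
    emits paired corrupted annotation sources with a ground-truth table
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
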