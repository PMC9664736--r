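Package: spliceoe
Title: Regional Splicing Constraint and Ensemble Prioritization of
    Splice-Altering Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds regional models of genetic constraint against aberrant
    splicing from population variant callsets and per-nucleotide splice
    predictions. Substitution probabilities are estimated per reference
    allele and splice-score bin, genes are tiled into windows, and a
    likelihood-weighted observed/expected statistic is rank-normalized into
    a [0,1] constraint score. A random-forest ensemble combines the
    regional constraint score with per-variant splice predictions to
    prioritize pathogenic splice-altering variants, with precision-recall
    and odds-ratio enrichment evaluation. Includes a synthetic-data
    generator that emulates genes, splice-score tracks, population
    variation under tunable purifying selection, and labeled truth sets so
    the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    methods,
    S4Vectors,
    purrr,
    ranger,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
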