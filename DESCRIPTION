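Package: scinet
Title: Coexpression Network Meta-Analysis of the Spinal Cord Injury Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative systems-biology toolkit for studying the
    transcriptional response to spinal cord injury. Builds signed weighted
    gene coexpression networks (biweight midcorrelation, soft thresholding,
    topological overlap, dynamic tree cut), quantifies module preservation
    across datasets with the permutation Zsummary statistic, validates
    curated gene sets against degree-preserving interactome null models
    (interaction enrichment, largest connected component, co-complex and
    shared-annotation tests, DIAMOnD seed recovery), performs module-level
    differential-expression meta-analysis with mean-rank gene-set tests and
    consensus calls, scores severity-dependent expression, and nominates
    hub-gene biomarkers by linear discriminant analysis with leave-one-out
    cross-validation. Ships a synthetic-data generator with planted module,
    interactome and severity structure so the full pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
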