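Package: ibdfilter
Title: Identity-by-Descent Filtering for Disease-Gene Discovery in
    Extended Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for prioritising disease genes in exome data from
    extended pedigrees by identity-by-descent (IBD) filtering. Distantly
    related affected relatives share only a small fraction of their
    genomes, so genes shared IBD by many case-case pairs form a compact
    candidate set. The package selects distant case-case pairs by
    realized genome sharing, ranks genes by the number of case subjects
    sharing them ("most cases" and "max cases" scoring), aggregates
    selections across phenotype replicates, filters variants by
    population frequency and predicted function, screens the survivors
    with a family-based association score test with empirical variance,
    and evaluates sensitivity against planted truth. A gene-drop
    simulator produces pedigrees, variant maps, true per-gene IBD
    scores, genotype dosages and replicate phenotypes with known causal
    genes, so the whole pipeline runs end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
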