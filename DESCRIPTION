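Package: famseg
Title: Family-Based Rare-Variant Co-Segregation and Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for prioritizing rare deleterious variants in
    multiplex-family sequencing studies of Mendelian and oligogenic disease.
    Implements a variant filtering cascade (functional class, predictor
    consensus, population allele frequency), pedigree-aware co-segregation
    filtering with dominant and compound-heterozygous models, in-cohort
    control exclusion, gene-intolerance (RVIS) binned enrichment z-scores,
    preranked weighted gene set enrichment analysis with a permutation null,
    gene-collapsed case/control carrier burden testing by Fisher's exact
    test, and CADD-based pathogenicity comparisons and variant ranking.
    Ships a Mendelian family-cohort simulator (pedigree templates, gene
    dropping, causal-variant planting, annotation emulation) so the whole
    pipeline can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    broom,
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
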