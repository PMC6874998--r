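Package: neocall
Title: Neoantigen Discovery and Cohort Statistics for Tumor Mutation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cohort-scale neoantigen discovery from somatic
    mutation data. Reads somatic mutations in MAF format together with per-sample
    HLA class-I genotypes, applies a population allele-frequency filter, enumerates
    mutant/wild-type 8-11mer peptide pairs around missense mutations, scores
    peptide-HLA binding with a family of position-specific scoring matrix (PSSM)
    predictors, and calls neoantigens by a multi-tool consensus rule (IC50 < 500 nM
    in at least two tools, mutant binding stronger than wild type). Cohort-level
    analyses cover per-sample neoantigen load, recurrent ("public") neoantigens,
    greedy panel selection with coverage, mutual-exclusivity screening of gene
    pairs, subgroup comparisons, and load-burden correlation, using exact
    small-sample tests. A synthetic-cohort generator with a ground-truth binding
    model makes every stage testable without patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
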