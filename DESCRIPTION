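Package: editscan
Title: Coverage QC, Cohort Variant Classification, and CRISPR Off-Target
    Attribution for Haploid Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of whole-genome sequencing of haploid
    (e.g. yeast) strain cohorts: per-base coverage-bias and
    breadth-of-coverage library metrics, GC-content sliding-window bias
    covariates, SNP-calling true/false positive rates against a gold
    standard, GATK-style hard filtering and cohort depth/missingness
    filtering of multi-sample variant calls, mutant-allele-frequency
    classification into background, private, shared and designed
    on-target variants, and attribution of private variants to
    CRISPR/Cas9 off-target activity by best-match Levenshtein scanning of
    variant-centered sequence windows against each strain's guide target.
    Includes a synthetic cohort generator (genomes, planted variants,
    brute-force-verified off-target-like sites, negative-binomial
    coverage tracks) so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
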