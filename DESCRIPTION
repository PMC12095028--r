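Package: trioprio
Title: Trio Exome Candidate-Gene Prioritization for Congenital Heart
    Disease and Laterality Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing candidate genes from
    whole-exome sequencing of affected-proband family trios. Implements
    depth, rarity and deleteriousness filtering of annotated variants;
    Mendelian inheritance-mode classification (de novo, autosomal
    recessive homozygous, compound heterozygous, X-linked recessive);
    intersection of loss-of-function variants with a configurable
    disease-gene list with LOEUF constraint and cilia annotation; an
    evidence-based five-tier variant classification; per-proband gene
    burden; and one-sided Fisher exact allele-count tests against
    reference populations. Ships a deterministic synthetic trio-cohort
    generator so every stage is testable without access to restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
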