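Package: cnvconverge
Title: Genotype-Phenotype Convergence Analysis for Rare Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for dissecting the genetic architecture of a rare
    complex disease from cohort-level copy-number-variant (CNV) calls and a
    common-variant candidate gene list. Implements multi-caller concordance
    merging, quality-control filtering and cohort-private CNV determination
    against reference panels; gene-dosage annotation by padded exon
    intersection; pathway enrichment with one-sided Fisher tests and
    Benjamini-Hochberg FDR tiers; a permutation-based protein-protein
    interaction inter-connectivity test between rare-CNV genes and
    common-variant candidate genes; candidate-network construction with
    module detection, centrality and core-periphery classification; and
    comorbidity prevalence and genotype-phenotype correlation matching.
    Ships a fully seeded synthetic-data generator that plants recoverable
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
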