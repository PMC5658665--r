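Package: recessid
Title: Recessive Intellectual-Disability Variant Prioritization and Brain
    Co-Expression Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pedigree-aware prioritization of recessive variants in
    consanguineous families via a seven-tier filtration cascade (quality,
    consequence, population frequency, recessive genotype model including
    compound heterozygotes, segregation, matched controls, in-silico
    pathogenicity), with loss-of-function classification from HGVS
    nomenclature and cohort-level summaries. Also implements thresholded
    Pearson co-expression networks per brain region and developmental
    stage, a within-gene-set edge-count statistic with a permutation null
    and Bonferroni correction, and an embryonic post-conception-week
    windowed variant of the same analysis. A synthetic-data module
    generates consanguineous pedigrees, gene-dropped genotypes, variant
    annotations, control cohorts and expression matrices with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
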