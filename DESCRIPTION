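Package: phyloconflict
Title: Genome-Wide Gene-Tree/Species-Tree Discordance Analysis Under the
    Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and explaining genome-wide phylogenetic
    conflict in rapid radiations of three lineages plus an outgroup. Classifies
    rooted gene trees against a species-tree backbone, filters them by
    cross-strategy consistency and bootstrap support, computes gene concordance
    factors, Robinson-Foulds distance matrices with classical multidimensional
    scaling, tests the incomplete-lineage-sorting null with a multispecies
    coalescent quartet test, detects introgression with the ABBA-BABA
    D-statistic and block-jackknife Z score, and simulates gene trees and
    biallelic site patterns under the multispecies coalescent with an optional
    introgression pulse so every stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
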