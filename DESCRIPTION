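Package: corrisoil
Title: Corrinoid Ecology of Soil Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the ecology of corrinoids (the vitamin B12
    family of cofactors) in soil microbiomes. Classifies genomes and
    metagenome-assembled genomes into corrinoid ecological roles (producer,
    dependent, independent, producer/non-user) from KO/Pfam annotation
    tables and tallies corrinoid-dependent versus -independent enzyme
    redundancy; calibrates a microbiological corrinoid bioassay (standard
    curve, limit of detection, saturation censoring); estimates the
    soil-water partition coefficient of corrinoids from serial-extraction
    series and back-extrapolates the soil corrinoid pool; and screens
    amplicon (zOTU) feature tables for corrinoid-responsive taxa across
    taxonomy levels with Bray-Curtis/Jaccard ordination, ANOSIM, PERMANOVA,
    Kruskal-Wallis and Mann-Whitney statistics. A synthetic-data generator
    produces ground-truthed inputs for every stage.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
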