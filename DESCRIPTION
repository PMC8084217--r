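Package: galeria
Title: Grazed Versus Restored Gallery-Forest Survey Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired grazed/restored gallery-forest
    monitoring surveys in forest-savanna mosaics: stand-structure summaries
    (densities and basal areas by life stage and functional group), size-class
    distributions, the Natural Regeneration index (NR/TNR) over sapling height
    classes, standardized principal-component ordination of shrub and
    ground-layer cover, line-transect wildlife encounter rates, and exact
    (analytic) species-accumulation curves over fixed-length survey segments.
    Includes a seeded synthetic field-survey generator that emulates the
    nested plot/transect/quadrat design so every estimator can be exercised
    and recovered against known generating parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
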