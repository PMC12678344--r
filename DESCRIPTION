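Package: sandfix
Title: Comprehensive Evaluation of Sand-Fixing Plantation Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the comprehensive, multi-indicator evaluation of
    dryland revegetation programmes that stabilise shifting sand with shrub
    plantations. The package computes plant community metrics (species
    importance values; Shannon, inverse Simpson, Pielou and Margalef
    diversity indices), soil physical and nutrient indicators (particle-size
    binning, bulk density and porosity, depth-profile aggregation),
    normalises heterogeneous indicators with a sigmoidal membership function,
    derives objective indicator weights from principal-component
    communalities, ranks land types by grey relational analysis (equal-weight
    and weighted relevance), and identifies drivers of the comprehensive
    score with a random-forest regression whose variable importance is tested
    by permutation. A synthetic study generator emulating a nested
    plantation/bare-sand sampling design makes the whole pipeline testable
    end to end without field data.
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
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
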