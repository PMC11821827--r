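Package: benthovuln
Title: Trait Vulnerability of Benthic Communities to Mass Mortality Events
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the vulnerability of benthic trait diversity to
    mass mortality events (MMEs). Builds functional entities (unique
    combinations of ten ecological traits), embeds them in a Euclidean trait
    space (Gower dissimilarity, principal coordinates, mean-absolute-deviation
    dimensionality selection), measures impacted convex-hull trait volumes
    across severity classes, mortality drivers, regions and time with balanced
    resampling of unbalanced survey effort, and fits zero-one-inflated beta
    Bayesian regressions of mortality severity on trait categories. Includes a
    synthetic-data generator that emulates the structure of Mediterranean MME
    compilations for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
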