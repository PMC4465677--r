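Package: occuCam
Title: Hierarchical Occupancy Models for Camera-Trap Detection Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw camera-trap image records into weekly
    detection histories and analysing them with hierarchical site-occupancy
    models that separate use of a site from imperfect detection. Three
    likelihood families are implemented: a multiseason single-species model
    with implicit dynamics, a multistate model with conditional occupancy and
    conditional detection of a focal age-sex class, and a two-species
    co-occurrence model. Model sets are ranked by AIC and summarised by
    Akaike-weight model averaging on the probability scale. A companion
    vegetation pipeline derives plant-composition covariates (cover-class
    importance values, Bray-Curtis similarity, non-metric multidimensional
    scaling, group-average clustering and SIMPER decomposition). Detection
    histories round-trip through a documented plain-text PAO-style format,
    and a seeded synthetic-data generator simulates covariate landscapes,
    camera effort and detections under each model family so every stage of
    the pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
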