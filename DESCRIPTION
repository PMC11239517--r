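Package: paleocomm
Title: Succession, Tiering and Composition Analysis of Benthic Palaeocommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative community ecology of census-style fossil
    bedding-plane assemblages. Reads specimen-level census maps, restores
    tectonically sheared surfaces by retrodeforming elongated holdfast discs,
    generates spatial jackknife subsamples by an expanding-box rule, builds
    taxon composition tables with sensitivity treatments for poorly preserved
    (effaced) fronds, ordinates and clusters communities with Bray-Curtis
    dissimilarity, quantifies ecological succession with abundance-biomass
    comparison curves and the W statistic (with confidence-interval based
    successional staging), and quantifies epifaunal tiering with exact
    interval-arithmetic distinct-vertical-stratification (DVS) metrics,
    including abundance-weighted variants. A synthetic community generator
    with planted composition, succession and tiering structure supports
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
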