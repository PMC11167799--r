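Package: bassgeo
Title: Archival-Tag Geolocation and Migration Analysis for European Sea Bass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs seasonal migrations of European sea bass
    (Dicentrarchus labrax) from archival data-storage tags. Provides
    simulation of depth/temperature tag archives over synthetic shelf-sea
    environments, tag-fate classification (predation, capture-and-discard,
    premature detachment), grid-based hidden-Markov-model geolocation with
    bathymetric, tidal and temperature-at-depth likelihood layers
    (forward-backward smoothing, diffusivity estimation and Viterbi
    decoding), and downstream migration, space-use and spawning metrics,
    together with packaged transcriptions of published electronic-tag and
    mark-recapture recovery tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
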