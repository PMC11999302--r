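Package: svindex
Title: Social Vulnerability Index Construction for Climate Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds small-area social vulnerability indices for climate
    hazards (flooding, extreme heat) from census-style indicator tables and
    a declared indicator/domain/dimension hierarchy. Indicators are z-score
    normalized and direction-aligned, weighted under a four-tier rule set
    that adapts to missing indicators, domains or dimensions (equal
    within-domain weights, halved weights for depleted domains, or a
    principal-component variance-proportion index when a whole dimension is
    absent), aggregated into domain, dimension and overall scores,
    classified into ordinal vulnerability bands, joined to area geometries
    (GeoJSON) and compared against reference indices by rank agreement.
    Ships hierarchy presets for flood (Irish-style census) and heat
    (Spanish/Italian-style census) plus a synthetic census-like data
    generator with a known latent vulnerability factor so every tier path
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
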