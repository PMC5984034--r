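Package: tractblueprint
Title: Comparative Cortical Anatomy with Connectivity Blueprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds connectivity blueprints -- row-stochastic (cortical
    vertex x white-matter tract) matrices derived from tractography -- and
    uses them as a common reference space for comparative anatomy.
    Fingerprints (blueprint rows) are compared within and across species
    with the symmetric Kullback-Leibler divergence in bits; whole cortical
    maps are transformed between species by divergence-weighted
    interpolation; region atlases are compared through region-level
    fingerprints and projected into a shared two-dimensional space by
    spectral embedding of their divergence structure.  A synthetic-data
    generator with planted homologies and divergent regions makes every
    operation testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
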