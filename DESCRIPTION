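Package: trophochem
Title: Chemical and Proteomic Characterization of Social-Insect Trophallactic Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the chemistry of trophallactic fluid and
    the cuticle of social insects from GC-MS and shotgun-proteomic data.
    Implements Kovats retention indices against an n-alkane ladder,
    identification of linear and methyl-branched long-chain hydrocarbons from
    electron-impact spectra (exponential-decay modelling of the alkyl fragment
    series, diagnostic-ion detection, branch-position inversion, retention-index
    consistency curves), chromatographic profile comparison by normalized
    cross-correlation with group testing and bootstrap hierarchical clustering,
    and NSAF spectral-count quantification with between-condition testing.
    Seeded synthetic-data generators emulate every input class so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    MASS,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
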