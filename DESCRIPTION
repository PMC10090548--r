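Package: ccmen
Title: Directional Preference of Cancer-Cell-Membrane-Coated Nanoparticles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic prediction of the fraction of a cancer-cell-membrane
    encapsulated nanoparticle (CCMEN) population directed towards glioblastoma
    cancer cells, normal healthy cells, or secreted soluble factors. Conditional
    binding efficiencies are derived from intrinsic protein-protein binding
    scores and differential surface-protein expression; all receptor
    combinations up to degree n are enumerated exhaustively, binding strengths
    are mapped to selective-propensity angles in a three-channel vector space,
    and population fractions, odds ratios and the break-even-point statistic
    are reported. Includes a packaged glioblastoma receptor/factor expression
    panel, a seeded synthetic affinity generator, ELISA logarithmic
    standard-curve fitting and percent-bound calculators, tabular CSV output
    families, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
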