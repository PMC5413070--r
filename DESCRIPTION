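Package: egctools
Title: Detection and Removal of Energy-Generating Cycles in Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based genome-scale metabolic models frequently admit
    energy-generating cycles (EGCs): sets of internal reactions that charge
    energy metabolites such as ATP or NADH, or build a transmembrane proton
    gradient, without any nutrient uptake.  Such cycles violate thermodynamics
    and inflate predicted biomass yields.  'egctools' detects EGCs by attaching
    energy-dissipation reactions for 15 energy currencies and maximising their
    flux with all exchanges closed (a flux-balance linear program), and repairs
    models by computing a globally minimal set of unidirectional reaction
    deactivations that eliminates every cycle while preserving biomass
    production, via a bi-level program contrasting a growth and a non-growth
    case, reformulated to a single-level mixed-integer program through duality.
    Includes SBML (Level 3, fbc) and JSON model I/O, model normalisation and
    mass/charge-balance screening, toy-model fixtures of published cycle
    motifs, a seeded random-model generator, batch reporting, and a small
    dense simplex and branch-and-bound solver used by all optimisations.
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
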