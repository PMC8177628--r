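Package: multibof
Title: Flux Balance Analysis with Environment-Dependent Biomass Objectives
Version: 0.1.0
Authors@R:
    person("Multibof", "Developers", email = "multibof@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models in
    which the biomass objective function (BOF) depends on the nutrient
    environment.  Provides model input/output (SBML Level 3 FBC and
    COBRA-style JSON), construction and mass-normalisation of biomass
    compositions, a linear-programming core (FBA, lexicographic secretion
    maximisation, parsimonious FBA, respiratory quotient), three
    multi-biomass methods -- Biomass Tradeoff Weighting (BTW), plane
    interpolation of biomass coefficients over nutrient uptake space (HIP)
    and its fixed-point iteration (HIP-I) -- plus phenotype phase-plane
    scans, single-gene knockout screens with growth-ratio binning, and an
    angle-based similarity score against experimental essentiality data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
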