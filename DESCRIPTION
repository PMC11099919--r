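Package: coform
Title: Virtual Cocrystal Screening and Solid-Form Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for knowledge-based cocrystal screening and solid-form
    analysis of active pharmaceutical ingredients. Implements hydrogen-bond
    donor/acceptor parameters derived from molecular electrostatic potential
    surface extrema and the associated cocrystal formation energy gain
    across stoichiometries, molecular-complementarity shape and polarity
    descriptors, post-processing of crystal-energy-landscape tables
    (formation energies, feasibility cutoffs, stoichiometry-corrected
    stability orderings, pairwise-interaction aggregation), and polymorph
    and solvate thermodynamics from differential scanning calorimetry and
    thermogravimetric observables (heat-of-fusion rule, transition
    temperature estimation, solvate stoichiometry). Seeded synthetic-data
    generators emulate quantum-chemistry and crystal-structure-prediction
    outputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
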