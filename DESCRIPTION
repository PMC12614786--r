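Package: crinvade
Title: Consumer-Resource Invasion Assays for Colonization Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microbial community assembly and invasion in a
    MacArthur-style consumer-resource model with byproduct leakage and a
    Dirichlet-generated metabolic conversion matrix. Random species pools
    with budget-constrained uptake preferences are assembled to steady
    state through dilution-propagation and perturbation filtering, then
    challenged with an invader; each trial is classified as augmentation,
    displacement, disruption, or resistance. Includes ensemble generators,
    parameter sweeps over resource supply, resource diversity, and
    cross-feeding parameters, bootstrap confidence intervals on outcome
    frequencies, and derived analyses such as richness-resistance curves
    and rank-abundance extinction profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
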