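Package: serialdil
Title: Serial Dilution Consumer-Resource Ecosystems with Metabolic
    Trade-Offs
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of microbial communities competing
    for substitutable nutrients in serial batch culture. Species are
    enzyme-allocation strategies on the nutrient simplex constrained by a
    shared (optionally noisy) enzyme budget; within-batch growth follows
    Monod uptake kinetics, integrated together with the per-nutrient
    Monod-function integrals that govern coexistence. Provides
    deterministic and stochastic (finite-cell bottleneck with spike-in
    migration) dilution protocols to steady state, the chemostat-limit
    steady-state condition, remapped coexistence boundaries, the
    convex-hull coexistence criterion, cross-feeding through metabolic
    byproducts, effective-species diversity summaries, and parameter
    sweeps of diversity against nutrient bolus size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: deSolve, grDevices, jsonlite, stats, utils
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
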