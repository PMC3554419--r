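Package: glycotherm
Title: Temperature Scaling and Metabolite Homeostasis in Yeast Glycolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of anaerobic yeast glycolysis under dynamic
    temperature regimes. Provides a reduced glycolysis network with
    Michaelis-Menten style rate laws, Ratkowsky square-root temperature
    scaling of enzyme capacities, Van't Hoff propagation of equilibrium
    constants, and bioreactor mass balances for batch and chemostat
    cultivation under constant, linearly shifted and circadian temperature
    profiles. Includes the downstream analysis: a collapse statistic that
    quantifies whether metabolite-versus-residual-glucose relations from
    different temperature regimes fall on a single curve, a permutation test
    for residual temperature dependence, localization of an enzyme whose
    catalytic capacity has a deviating temperature sensitivity, and a
    synthetic-measurement generator that emulates duplicate sampling with
    multiplicative noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
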