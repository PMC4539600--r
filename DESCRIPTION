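Package: RootCrosstalk
Title: Spatiotemporal Modelling of Hormonal Crosstalk in the Arabidopsis Root
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-dimensional multicellular finite-volume simulator of
    hormonal crosstalk in the Arabidopsis thaliana root tip. The model couples
    reaction kinetics of auxin, ethylene and cytokinin, the POLARIS (PLS)
    peptide, the ethylene receptor-CTR1 signalling cascade, and dynamic
    expression and membrane recycling of the PIN and AUX1 auxin carriers with
    diffusive and carrier-mediated transport on a gridded root map. Steady
    states are obtained by implicit pseudo-time stepping with Picard
    linearisation and preconditioned conjugate-gradient linear solves.
    Genotype configurations (wild type, pls, etr1, pls etr1, PLSox, aux1)
    reproduce observed levels, patterns and trends of hormones, PIN and PLS
    proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
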