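Package: hippomech
Title: Coupled Hippo-Pathway Signaling and Tissue Mechanics in the Drosophila Wing Disc
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growth control in the Drosophila wing disc by coupling
    three models: an ordinary-differential-equation model of the upstream Hippo
    pathway (Fat/Dachsous/Four-jointed regulation of Dachs and Riquiqui,
    Expanded-dependent Warts activation, and Warts-dependent Yorkie
    inactivation), a force-dependent three-state model of alpha-catenin
    unfolding with Bell-type transition rates and state-dependent Ajuba (Jub)
    binding, and a viscoelastic Kelvin-Voigt cell-network model of a seven-cell
    hexagonal patch with active contractility and rest-length growth. The
    coupled model propagates junctional tension through alpha-catenin and Jub
    into Warts sequestration and Yorkie activity, and Yorkie activity back into
    tissue growth. Includes experiment presets for parameter scans
    (Fat production, tension by alpha-catenin level, centre-cell perturbations,
    Jub production) and tidy CSV/JSON result writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
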