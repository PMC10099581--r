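Package: stepscale
Title: Scaling Up Step-Selection Movement Kernels to Space-Use Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for propagating parametrised step-selection movement kernels
    to broad-scale space-use patterns. Builds movement kernels on rasterised
    landscapes (selection-free step-length component times an exponential
    habitat-selection term, normalised over the study area), propagates
    utilisation distributions forward in time with the discretised master
    equation, solves for steady states numerically (power iteration, eigen
    decomposition) and in closed form (Barnett-Moorcroft steady state and its
    resource-selection and doubled-selection limits), simulates single and
    coupled individual-based movement models with occurrence-distribution
    feedback, and computes home-range overlap and size metrics
    (Bhattacharyya's affinity, locational variance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
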