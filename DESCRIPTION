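Package: connectomeRD
Title: Reaction-Diffusion Dynamics on Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the spread of damage or pathological substance on a
    structural brain connectome as reaction-diffusion dynamics on a graph.
    Provides connectome thresholding into a binary graph, the graph Laplacian
    and its heat-kernel (network diffusion) solution, reaction-diffusion ODE
    integration with logistic, strong-Allee and neutral-Allee reaction terms,
    the summary observables M(t) (mean concentration) and N(t) (nodes above a
    concentration threshold), outcome classification and invasion-value
    estimation by bisection, plus a synthetic connectome generator that
    emulates published whole-brain graph statistics so the full toolchain is
    testable without restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
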