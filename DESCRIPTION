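Package: hscniche
Title: Competition Models of Healthy and Leukaemic Haematopoiesis in the
    Stem Cell Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic competition models of healthy and leukaemic
    haematopoiesis in the bone-marrow niche. Two five-species ordinary
    differential equation models (with and without a negative feedback of
    differentiated blood cells on progenitor differentiation) are provided
    with closed-form steady states, critical parameter values bounding the
    coexistence region, linear stability analysis via analytic Jacobians,
    stiff numerical integration to equilibrium (LSODA, compiled
    right-hand sides), and parameter-space sweep machinery that classifies
    survival, coexistence and lineage dominance over grids or seeded
    uniform samples and aggregates them into probability summaries and
    two-dimensional density tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
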