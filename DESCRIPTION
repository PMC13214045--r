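Package: erscaling
Title: Expansion-Repression Morphogen Gradient Models with
    Position-Dependent Expanders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a modified expansion-repression (ER)
    reaction-diffusion circuit in which a diffusing expander molecule
    suppresses morphogen degradation while the morphogen represses
    expander production and the expander additionally represses its own
    degradation. Provides stiff method-of-lines steady-state and
    transient solvers with zero-flux boundaries, closed-form limiting
    gradients as analytic oracles, position-dependent metrics of
    gradient scaling, robustness to production-rate perturbation, and
    positional precision, plus a seeded log-uniform parameter-sweep
    protocol that maps how the expander's dynamic range trades off these
    patterning properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
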