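Package: ionmodl
Title: Layer-Oriented Compiler for Conductance-Based Ionic-Current Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A declarative, layer-oriented model-description language for
    Hodgkin-Huxley-style conductance-based models of ionic currents.
    Hierarchical model descriptions written in a parenthesized (s-expression)
    syntax or an equivalent XML dialect are parsed into a common syntax tree,
    lowered through semantic transformation functions (gating dynamics,
    Markov kinetic schemes, Ohmic and Goldman-Hodgkin-Katz current laws,
    calcium pool dynamics, membrane-potential assembly, component
    flattening) to a flat ordered system of ordinary differential equations,
    and emitted as executable code for several targets: an R solver
    right-hand side, a Matlab/Octave-style script, and NMODL mechanism files
    with optional automatic merging of mechanisms. Includes a reference
    integrator built on deSolve, steady-state initialization, voltage-clamp
    experiment generation, bundled Hodgkin-Huxley and Purkinje-neuron style
    model fixtures, and a random model generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
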