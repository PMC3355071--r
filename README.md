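# ionmodl

A layer-oriented, declarative model-description language and compiler for
conductance-based models of ionic currents, implemented in R.

Computational neuroscientists describe ion-channel models in terms of
biological concepts — channel gates, maximal conductances, permeating ions,
Markov kinetic schemes, calcium pools — but every simulator wants something
different: NEURON wants NMODL mechanism files, Matlab/Octave wants a
right-hand-side function for an ODE solver, and a reference implementation
wants plain equations. Transcribing a published model by hand for each
target is slow and error-prone, and merging several NMODL mechanisms into
one file (which speeds up simulation) invites name collisions.

`ionmodl` addresses this with a small hierarchical language and a chain of
semantic transformation functions that lower each biological concept to
equations:

* a **gating** declaration with rates α(V), β(V) and power p becomes
  dm/dt = α(V)(1 − m) − β(V)m, contributing mᵖ to the conductance
  product; the `hh-gating-dynamics` template accepts the equivalent
  (m∞, τ) parameterization, dm/dt = (m∞(V) − m)/τ(V);
* a **kinetic scheme** (Markov model) with mass-action transitions becomes
  one ODE per state, with total occupancy conserved and the conductance
  proportional to the open-state occupancy;
* an **Ohmic current** becomes i = ḡ · ∏ gates^p · (V − E); a **GHK
  current** becomes i = p̄ · ∏ gates^p · Φ(V, cᵢ, cₒ, z), where Φ is the
  Goldman–Hodgkin–Katz constant-field flux
  Φ = z²F²V/(RT) · (cᵢ − cₒ e^(−zFV/RT)) / (1 − e^(−zFV/RT));
* a **decaying pool** becomes the Traub-style concentration equation
  dc/dt = −b·i − (c − c∞)/τ, its output wired into other components by
  `input` declarations;
* the **membrane potential** is assembled from every current:
  dV/dt = −(Σᵢ iᵢ)/C (plus an optional applied current).

Components nest, declare outputs, and are *flattened* into a single
namespace with path-prefixed names — which is exactly what makes automatic
NMODL mechanism merging collision-free. Models can be written in a concise
parenthesized (s-expression) syntax or an equivalent XML dialect; the two
are fully interchangeable.

## Worked example

The classic Hodgkin–Huxley squid-axon model ships as a fixture, in the
shifted convention (rest at 0 mV, E_Na = 115 mV, ḡ_Na = 120 mS/cm²,
C = 1 µF/cm²):

```r
library(ionmodl)
m <- compile_model(hh_fixture())
m
#> <model 'HH': 4 state(s), 3 current(s)>
names(m$sys$state_index)
#> [1] "v"    "Na_m" "Na_h" "K_n"

round(steady_state_init(m$sys, 0), 4)
#>      v   Na_m   Na_h    K_n
#> 0.0000 0.6414 0.5961 0.3177
```

The gates initialize at α/(α+β): with the model's printed sodium rates,
m∞(0) = 0.6414. A 50 ms run under a 20 µA/cm² stimulus produces a
full-height action potential:

```r
tr <- simulate_model(m$sys, duration = 50, stim = 20,
                     times = seq(0, 50, 0.025))
max(tr$v)                      # peak of the action potential, mV
#> [1] 111.6899
sum(diff(tr$v > 50) == 1)      # upward crossings of +50 mV
#> [1] 1
```

Code generation targets R (`emit_solver_function`), Octave/Matlab
(`emit_octave_script`) and NEURON's NMODL (`emit_nmodl`), the latter with
automatic merging:

```r
cat(names(emit_nmodl(m$sys, m$info, merge = FALSE)))
#> Na.mod K.mod Leak.mod
cat(emit_nmodl(m$sys, m$info, merge = TRUE)[["HH.mod"]])
#> NEURON {
#>   SUFFIX HH
#>   USEION na READ ena WRITE ina
#>   USEION k READ ek WRITE ik
#>   NONSPECIFIC_CURRENT Leak_i
#>   ...
```

A richer fixture, `kr_fixture()`, reconstructs the structure of the 2003
Khaliq–Raman Purkinje-neuron model: a 13-state resurgent-sodium kinetic
scheme, a GHK calcium current wired to a decaying calcium pool, and the
printed CaBK voltage-clamp protocol (hold −90 mV, steps from −40 mV in
10 mV increments). `run_clamp()` simulates the protocol;
`generate_clamp_script()` emits it as a standalone script.

A command-line front end is included (`inst/cli/ionmodl`, or
`run_cli()` from R) with `compile`, `simulate`, `clamp`, `validate` and
`convert` subcommands.

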