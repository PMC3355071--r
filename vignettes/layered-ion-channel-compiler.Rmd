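---
title: "A layer-oriented compiler for conductance-based ionic-current models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layer-oriented compiler for conductance-based ionic-current models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionmodl)
```

## The idea

`ionmodl` treats an ion-channel model not as a flat list of equations but
as a stack of small declarative languages ("layers"), each matching how a
particular level of the model is actually discussed: an *ionic-current
layer* (gates, pores, permeating ions, pools), a *component layer*
(typed, named, output-declaring containers that nest and wire into each
other), and an *equation layer* (constants, algebraic assignments,
relations, rate equations, kinetic reactions). Between layers sit
semantic transformation functions that lower each concept to the layer
below, ending in a flat, dependency-ordered system of ODEs from which
executable code is generated for several targets. Every construct of the
surface language therefore has exactly one mathematical reading, and
adding a current law (the constant-field GHK law, for instance) means
adding one transformation clause, not a new simulator back end.

## The surface language

Models are written in a parenthesized syntax (or an equivalent XML
dialect; `parse_sexpr()`/`parse_xml()` produce element-wise identical
trees and `write_sexpr()`/`write_xml()` invert them byte-stably):

```
(Membrane-potential HH
 (Membrane-capacitance 1.0 uF/cm*cm)
 (Ohmic-current Na (E = 115 mV) (g_max = 120 mS/cm*cm)
  (gating m (power 3)
   (forward-rate (2.5 - 0.1*V)/((exp (2.5 - 0.1*V)) - 1))
   (reverse-rate (0.125 * exp(-V/80))))
  ...))
```

Grammar notes, all deliberate:

* Expressions are infix with `+ - * / ^`; function application is
  accepted both as `exp(x)` and `(exp x)`, since model listings in the
  field mix the two styles freely.
* Identifiers may contain `-` (`holding-duration`); consequently `a-b`
  without surrounding whitespace is one identifier, and subtraction must
  be written with spaces (or with numeric/parenthesized operands, as in
  `0.1*V - 1`).
* A unit annotation is an identifier-like token directly following a
  numeric literal (`1.0 uF/cm*cm`, `115 mV`). Units are carried as opaque
  strings and echoed on output; they are **not** dimensionally checked.
  The documented convention that makes `dv/dt = -i/C` consistent is mV,
  ms, mS/cm², µF/cm², µA/cm², mM.
* Kinetic schemes use a reconstructed concrete syntax (the scheme
  notation in the field is usually diagrammatic):
  `(reaction z (transitions (<- S1 S2 (fwd) (rev)) ...) (conserve 1)
  (open O (power p)))`, with forward-only transitions written
  `(<- S1 S2 (fwd))`. `conserve` defaults to 1 (occupancy
  probabilities), `power` to 1.

## Lowering semantics

**Gates.** `(gating m (power p) (forward-rate a) (reverse-rate b))`
expands to two rate relations `alpha_m(v)`, `beta_m(v)` and the equation
`dm/dt = alpha_m(v)(1-m) - beta_m(v)m`; the current assembly contributes
the factor `m^p`. The `hh-gating-dynamics` template is the (m∞, τ) form;
it is a component whose body must contain entities named *exactly*
`<gate>_inf` and `tau_<gate>` — any other name is an error, which is the
point of a template.

**Kinetic schemes.** Each state `s` receives
`ds/dt = Σ inflow − Σ outflow` under mass action. The emitted
derivatives cancel symbolically, so `Σ states` is a linear invariant of
the exact flow; the test suite checks it holds to 1e−8 along integrated
trajectories, and `steady_state_init()` solves the linear steady state
under the conservation constraint (replacing one balance row by the
conservation row; a singular system is reported as an error).

**Current laws.** Ohmic: `i = gbar·∏gates·(v − E)`. GHK:
`i = pmax·∏gates·ghk(v, ci, co, z, celsius)` with
F = 96485.33212 C/mol and R = 8.31446 J/(mol·K) (the standard CODATA-ish
values; model texts in this area typically do not state them).
Temperature enters through the model parameter `celsius`, default 22 °C.
The removable singularity of the constant-field expression at v = 0 is
evaluated by its first-order series `zF[(ci−co) + u(ci+co)/2]` when
`|u| = |zFv/RT| < 1e−6`; this makes the v→0 limit exactly `zF(ci−co)`
and keeps the symmetric-concentration case exactly linear in `v`. A
current is GHK precisely when it contains a `permeability` component
(instead of a `pore`); it then requires a `permeating-ion` with a
`valence` and inside/outside concentrations named `<ion>i`/`<ion>o`,
either defined locally or wired in.

**Pools.** `decaying-pool` lowers to the Traub-style decay
`dc/dt = −b·Σ i_src − (c − steady)/τ` and exports the concentration
under its declared output name; `input (cai from decaying-pool ca)`
binds the global `cai` to that export. The rate equations of the
sodium-activation singularity at `V = 25` in the bundled HH rates
(denominator `exp(0) − 1`) are left unguarded: adaptive integrators step
over the point and the generated code is required to behave identically
to the reference evaluator (infinities and NaN propagate rather than
raise).

**Membrane potential.** `dv/dt = (i_stim − Σ i_current)/C`, summing
Ohmic and GHK currents alike. The printed form of this equation in the
literature often elides the derivative; the rate reading is the only one
consistent with producing a time course. `i_stim` is a reserved symbol
(default 0) so that a stimulus can be applied without editing the model;
it appears as an argument of the emitted solver functions.

**Structure rules.** Exactly one `Membrane-capacitance`; at least one
current; per current exactly one conductance source (a `pore`, a
`permeability`, or a compact `g_max` parameter) and at most one
`permeating-ion`. Gating subcomponents are *optional*: the canonical HH
listing itself contains an ungated leak current, so an empty gate product
(= 1) is legal; a leak's species is the `non-specific` token, which maps
to `NONSPECIFIC_CURRENT` in NMODL.

## Flattening and naming

Nested environments are flattened by prefixing each entity with its
component path (names joined with `_`; unnamed components contribute
their type) and rewriting every expression through chained substitution
environments — inner frames shadow outer ones, and identifiers absent
from every frame pass through unchanged (the substitution operation
itself is total; the *flattening* pass separately rejects identifiers
that resolve nowhere, naming the offender). Gate equations are hoisted
into their current's namespace so the lowered names read like the
hand-written ones (`Na_m`, `Na_alpha_m`). Reserved globals `v`, `t`,
`celsius`, `i_stim` and wired inputs are never mangled; `V` in source is
normalized to `v`. Collisions after flattening are an error, and the
property suite checks injectivity over hundreds of generated models.
This collision-free renaming is exactly what makes merged NMODL safe.

## Ordering and the solver-ready form

`order_entities()` topologically sorts parameters and assignments by the
free variables of their right-hand sides (states and reserved globals are
roots; ties break by stable source order so generated code is
diff-able). Circular assignments and mutually recursive relations are
reported with the cycle. `build_ode_system()` then produces the ordered
definitions, the relation list (relations stay callable functions; they
are never inlined), the ODE list with kinetic schemes expanded one
equation per state, and a dense 0-based state index with `v` first.

## Code generation

The R target emits a self-contained bundle (`rhs`, `init`, `currents`,
`states`); the Octave/Matlab target emits a script with one function per
relation (constant parameters are inlined into each function body, since
file-level functions cannot see script variables) and an `lsode` driver.
Emission is canonical — fixed ordering, fixed formatting — so identical
systems yield byte-identical text, which the cross-target test exploits:
the interpreted reference right-hand side and the emitted-and-parsed one
evaluate the same expressions and their integrated voltage traces agree
to well below 1e−6 relative.

NMODL (NEURON 7.x dialect): one mechanism per current plus one per pool,
or a single merged mechanism. HH gates solve with `cnexp`, kinetic
schemes with `sparse` KINETIC blocks carrying a CONSERVE statement;
INITIAL sets gates to α/(α+β) (or m∞) and schemes to
`STEADYSTATE sparse`. Ion bookkeeping follows NEURON's fixed
conventions: lowercase species tokens, `e<ion>`/`i<ion>`/`<ion>i`
names, `USEION ... READ ena WRITE ina`, `VALENCE` on GHK calcium
currents, pools `READ ica WRITE cai`. Reversal potentials are kept as
mechanism-local RANGE parameters (initialized from the model text) — a
common published-mechanism style — while the USEION interface is still
declared. In a standalone pool mechanism the source-current sum is
replaced by the species current `i<ion>` (so multi-source pools of one
species are summed by NEURON itself; a pool fed by several currents maps
exactly only in merged mode). Block order within a `.mod` file beyond
NEURON's requirements is fixed by the emitter for byte-stable output.

## Experiments

`(simulation ...)` supplies `duration` and `stepsize` (both mandatory;
the step size is passed to fixed-step targets, while the reference
integrator is adaptive and uses it only as a reporting hint).
`(voltage-clamp (name X) ...)` must name an existing current. Two
conventions here are package choices, documented because the source
notation fixes only the parameter names: command voltages ascend from
`base` in `stepsize` increments (`base + k·stepsize`,
k = 0…nsteps−1 — the standard I–V protocol direction), and each sweep is
hold → command with no tail step, since only holding and base phases are
parameterized. Clamping replaces the membrane-potential equation with
`dv/dt = 0` (the potential is set per phase); every other equation is
untouched, and the suite asserts exactly that.

## Reference runtime

`simulate_model()` integrates with deSolve's `lsoda` (stiff-capable,
adaptive) at rtol 1e−7 / atol 1e−9 by default — channel kinetics,
especially multi-state schemes, are stiff — and reports on a grid of
2001 points unless told otherwise; the reporting grid is decoupled from
the solver's internal steps. Tightening the tolerances tenfold changes
the HH voltage trace by far less than 1e−3 mV RMS (checked in the
suite). `steady_state_init()` is the recommended initial condition;
the *emitted* `init` constructors use the same closed forms for HH gates
but a uniform occupancy for kinetic schemes (solving a linear system in
generated code buys little, since any long simulation relaxes the scheme
and NMODL's `STEADYSTATE sparse` does it natively in NEURON).

## Fixtures and the random-model generator

`hh_fixture()` is the canonical squid-axon listing in the shifted
convention (rest 0 mV, E_Na 115 mV, ḡ_Na 120 mS/cm², C 1 µF/cm²,
simulation 2000 ms / 1e−4 ms), with the sodium activation rates as
printed — note the reverse rate `0.125·exp(−V/80)`, which puts m∞(0)
near 0.64 — and the elided gates completed with the classical rate
functions. `kr_fixture()` reconstructs the component structure of the
2003 Khaliq–Raman Purkinje model: the 13-state Raman–Bean resurgent
sodium scheme (5 closed, 5 inactivated, open, blocked, open-inactivated;
topology and rate constants from the published model literature), a
Kv3-type current written with the template, a simplified CaBK current, a
leak, a GHK P-type calcium current wired to a decaying calcium pool
(pool constants are fixture choices of plausible magnitude), and the
printed CaBK clamp protocol. It is a *reconstruction*: where the
original supplementary listing is not available to this package, rate
bodies are simplified stand-ins with Purkinje-like voltage dependence,
so the fixture exercises every language feature and the printed
experiment constants but does not claim to reproduce the original
model's traces.

`random_model(seed, n_currents)` generates structurally valid models for
property testing: a capacitance plus `n_currents` currents with 1–2
gates of power 1–4, rate functions drawn from bounded exponential
`A·exp(±(v−B)/C)` and sigmoid `A/(1+exp(∓(v−B)/C))` families with
A ∈ [0.05, 3], B ∈ [−40, 40], C ∈ [15, 60] (positive, finite, no
blow-up over physiological voltages), occasional 3-state kinetic schemes
and GHK currents with constant concentrations, and both the compact and
the structured component spellings. The same seed yields byte-identical
text and the caller's RNG stream is preserved. What passing these
property tests shows is that parsing, flattening, ordering and emission
are total and collision-free on well-formed inputs; it says nothing
about biophysical plausibility of the generated dynamics, and the
generator deliberately avoids the singular rate forms (e.g. the
`(exp(x) − 1)` denominators) that real models do contain — those are
covered by the fixtures instead.

## Problem sizes used by the checks

The bundled checks run the HH fixture for 50 ms under a 20 µA/cm²
stimulus (2001 output points), the Purkinje-style fixture for its
declared 2000 ms (1 ms reporting), oracle comparisons at 100 random
state points, and pipeline robustness over 500 seeded random models —
sizes at which every behaviour of interest (spiking, scheme relaxation,
conservation, collision-freedom) is already expressed.

## Known limitations

* No conditional expressions, events, regimes, stochastic equations, or
  spatial/multi-compartment constructs; one membrane compartment.
* Units are syntax, not semantics: nothing is dimensionally checked.
* One permeating ion per current; multiple `permeating-ion` components
  are rejected.
* NMODL output is not compiled or run against NEURON here; the merge
  equivalence is established by an internal equation reader, and runtime
  performance of merged mechanisms is out of scope.
* The Octave target is emitted and structurally tested but not executed
  by the suite.
* Relation bodies are assumed to depend only on their formals and on
  constant parameters; a relation reading a state variable is not
  supported by the code generators.
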