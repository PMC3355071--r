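# Ionic-current layer: lowering of biological concepts (gates, kinetic
# schemes, Ohmic and GHK current laws, calcium pools, the membrane
# potential) to equations.

# Physical constants (SI). The model-level unit convention is: potentials in mV,
# time in ms, concentrations in mM (numerically equal to mol/m^3),
# conductances in mS/cm^2, capacitance in uF/cm^2; with these, dv/dt =
# -sum(i)/C is dimensionally consistent. Units are carried as opaque
# annotations and never checked.
.FARADAY <- 96485.33212   # C/mol
.GAS_R <- 8.31446         # J/(mol K)

validation_error <- function(msg) im_error(msg, "im_validation_error")

#' Gate specification
#'
#' One Hodgkin-Huxley-style channel gate: a state variable in `[0, 1]`
#' raised to an integer power in the conductance product, with dynamics
#' given either by forward/reverse rate functions of the membrane potential
#' or by a steady-state/time-constant pair.
#'
#' @param name Gate (state variable) name.
#' @param power Positive integer exponent in the conductance product.
#' @param forward,reverse Rate expressions (alpha, beta), or `NULL`.
#' @param inf,tau Steady-state and time-constant expressions, or `NULL`.
#' @param initial Initial value, or `"steady-state"` (the default) to
#'   initialize at alpha/(alpha+beta) resp. inf at the initial potential.
#' @export
gate_spec <- function(name, power = 1, forward = NULL, reverse = NULL,
                      inf = NULL, tau = NULL, initial = "steady-state") {
  power <- as.integer(power)
  if (is.na(power) || power < 1L) {
    validation_error(sprintf("gate '%s': power must be a positive integer",
                             name))
  }
  ab <- !is.null(forward) || !is.null(reverse)
  it <- !is.null(inf) || !is.null(tau)
  if (ab == it || (ab && (is.null(forward) || is.null(reverse))) ||
      (it && (is.null(inf) || is.null(tau)))) {
    validation_error(sprintf(
      "gate '%s': exactly one rate form (forward+reverse or inf+tau) required",
      name))
  }
  structure(list(name = name, power = power, forward = forward,
                 reverse = reverse, inf = inf, tau = tau, initial = initial),
            class = "im_gate_spec")
}

prefix_names <- function(path) {
  p <- paste(path, collapse = "_")
  function(nm) if (nzchar(p)) paste(p, nm, sep = "_") else nm
}

#' Expand an HH gate into entities
#'
#' The rate form yields two rate relations and the gating equation
#' `d(m)/dt = alpha_m(v) * (1 - m) - beta_m(v) * m`; the inf/tau form
#' yields `d(m)/dt = (m_inf - m) / tau_m`. The per-gate conductance factor
#' `m^power` is contributed by the current assembly (see
#' [assemble_ohmic_current()]).
#'
#' @param g A [gate_spec()].
#' @param path Scope path (character vector) used to prefix the generated
#'   names, or `NULL` for local names (the flattening pass prefixes later).
#' @return List of entities (relations first, then the RATE).
#' @export
expand_hh_gating <- function(g, path = NULL) {
  pre <- prefix_names(path %||% character(0))
  n <- g$name
  if (!is.null(g$forward)) {
    a_name <- pre(paste0("alpha_", n))
    b_name <- pre(paste0("beta_", n))
    state <- pre(n)
    rhs <- ex_bin("-",
      ex_bin("*", ex_app(a_name, list(ex_sym("v"))),
             ex_bin("-", ex_num(1), ex_sym(state))),
      ex_bin("*", ex_app(b_name, list(ex_sym("v"))), ex_sym(state)))
    list(ent_relation(a_name, "v", g$forward),
         ent_relation(b_name, "v", g$reverse),
         ent_rate(state, rhs))
  } else {
    state <- pre(n)
    rhs <- ex_bin("/", ex_bin("-", g$inf, ex_sym(state)), g$tau)
    list(ent_rate(state, rhs))
  }
}

#' Expand a kinetic scheme into per-state rate equations
#'
#' Mass-action lowering of a Markov scheme: each state s gets
#' `ds/dt = sum(inflow) - sum(outflow)` over its transitions. The symbolic
#' sum of all emitted derivatives cancels, so the total occupancy
#' `sum(states) = conserve` is invariant along any exact trajectory.
#'
#' @param r A REACTION entity (see [build_entity()]).
#' @param path Optional scope path prefixing state names.
#' @return List of RATE entities, one per state, in declaration order.
#' @export
expand_reaction <- function(r, path = NULL) {
  if (!is_entity(r) || r$kind != "REACTION") {
    validation_error("expand_reaction expects a REACTION entity")
  }
  pre <- prefix_names(path %||% character(0))
  gains <- stats::setNames(vector("list", length(r$states)), r$states)
  losses <- gains
  push <- function(lst, state, term) {
    lst[[state]] <- c(lst[[state]], list(term))
    lst
  }
  for (tr in r$transitions) {
    fwd_term <- ex_bin("*", tr$fwd, ex_sym(pre(tr$src)))
    gains <- push(gains, tr$dst, fwd_term)
    losses <- push(losses, tr$src, fwd_term)
    if (!is.null(tr$rev)) {
      rev_term <- ex_bin("*", tr$rev, ex_sym(pre(tr$dst)))
      gains <- push(gains, tr$src, rev_term)
      losses <- push(losses, tr$dst, rev_term)
    }
  }
  sum_terms <- function(terms) {
    if (length(terms) == 0L) return(NULL)
    Reduce(function(a, b) ex_bin("+", a, b), terms)
  }
  lapply(r$states, function(s) {
    gsum <- sum_terms(gains[[s]])
    lsum <- sum_terms(losses[[s]])
    rhs <- if (is.null(gsum) && is.null(lsum)) {
      ex_num(0)
    } else if (is.null(gsum)) {
      ex_neg(lsum)
    } else if (is.null(lsum)) {
      gsum
    } else {
      ex_bin("-", gsum, lsum)
    }
    ent_rate(pre(s), rhs)
  })
}

## ------------------------------------------------------------- GHK ----

#' Goldman-Hodgkin-Katz constant-field flux
#'
#' Current density per unit permeability for an ion of valence `z` crossing
#' a membrane at potential `v` (mV) with inside/outside concentrations
#' `ci`, `co` (mM, numerically mol/m^3):
#' \deqn{I/P = z^2 F^2 V / (RT) \cdot (c_i - c_o e^{-u}) / (1 - e^{-u}),
#'   \quad u = zFV/(RT)}
#' with Faraday constant F = 96485.33212 C/mol and gas constant
#' R = 8.31446 J/(mol K). The removable singularity at `v = 0` is handled
#' by the first-order series \eqn{zF[(c_i - c_o) + u (c_i + c_o)/2]} when
#' `|u| < 1e-6`, so the limit at 0 is exactly `z F (ci - co)` and symmetric
#' concentrations give a law linear in `v`.
#'
#' @param v Membrane potential in mV.
#' @param ci,co Inside/outside concentrations (mM), both non-negative.
#' @param z Integer valence, nonzero.
#' @param celsius Temperature in degrees Celsius (default 22).
#' @return Current density per unit permeability (A/m^2 per m/s, with the
#'   stated unit convention); positive values are outward.
#' @examples
#' ghk_flux(0, 1e-4, 2.4, 2)      # inward calcium flux at 0 mV
#' @export
ghk_flux <- function(v, ci, co, z, celsius = 22) {
  if (any(z == 0)) validation_error("ghk_flux: valence z must be nonzero")
  temp <- celsius + 273.15
  u <- z * .FARADAY * (v * 1e-3) / (.GAS_R * temp)
  small <- abs(u) < 1e-6
  ub <- ifelse(small, 1, u)   # keep the full formula finite where unused
  full <- z * .FARADAY * ub * (ci - co * exp(-ub)) / (1 - exp(-ub))
  series <- z * .FARADAY * ((ci - co) + u * (ci + co) / 2)
  ifelse(small, series, full)
}

## ------------------------------------------------ current assembly ----

#' Current specification
#'
#' Normalized description of one membrane current, as gathered from an
#' `Ohmic-current` component: the current law (OHMIC or GHK), the
#' permeating ion, the gate factors, and the names of the conductance /
#' permeability, reversal and concentration quantities in the flattened
#' namespace.
#'
#' @param name Current (component) name.
#' @param law `"OHMIC"` or `"GHK"`.
#' @param ion Ion species token (lowercase), or `"non-specific"`.
#' @param gates List of `list(state =, power =)` factors (open-state
#'   occupancies for kinetic schemes).
#' @param gbar Conductance (OHMIC) or maximal permeability (GHK) name.
#' @param e_rev Reversal-potential name (OHMIC only).
#' @param conc_in,conc_out Concentration names (GHK only).
#' @param valence Integer valence (GHK only).
#' @export
current_spec <- function(name, law = c("OHMIC", "GHK"), ion, gates = list(),
                         gbar, e_rev = NA_character_,
                         conc_in = NA_character_, conc_out = NA_character_,
                         valence = NA_integer_) {
  law <- match.arg(law)
  if (law == "OHMIC" && is.na(e_rev)) {
    structural_error(sprintf("Ohmic current '%s' needs a reversal potential",
                             name))
  }
  if (law == "GHK") {
    if (is.na(valence) || valence == 0L) {
      validation_error(sprintf("GHK current '%s' needs a nonzero valence",
                               name))
    }
    if (is.na(conc_in) || is.na(conc_out)) {
      im_error(sprintf(
        "GHK current '%s': internal/external concentrations are not defined or wired",
        name), "im_unresolved_error")
    }
  }
  structure(list(name = name, law = law, ion = ion, gates = gates,
                 gbar = gbar, e_rev = e_rev, conc_in = conc_in,
                 conc_out = conc_out, valence = valence),
            class = "im_current_spec")
}

gate_product <- function(gates) {
  factors <- lapply(gates, function(g) {
    s <- ex_sym(g$state)
    if (g$power == 1L) s else ex_bin("^", s, ex_num(g$power))
  })
  if (length(factors) == 0L) return(NULL)
  Reduce(function(a, b) ex_bin("*", a, b), factors)
}

#' Assemble the equations of an Ohmic current
#'
#' Produces the conductance `g_<name> = gbar * prod(gates^power)`, the
#' current `i_<name>_raw = g * (v - E)` and the model-level current alias
#' `i_<name>`; names follow the flattened `<name>_g`, `<name>_i` scheme.
#'
#' @param c A [current_spec()] with `law = "OHMIC"`.
#' @param path Optional scope path (prefix) for the generated names.
#' @return List of entities.
#' @export
assemble_ohmic_current <- function(c, path = NULL) {
  stopifnot(inherits(c, "im_current_spec"))
  if (c$law != "OHMIC") validation_error("assemble_ohmic_current: law must be OHMIC")
  pre <- prefix_names(path %||% character(0))
  g_name <- pre(paste0(c$name, "_g"))
  i_name <- pre(paste0(c$name, "_i"))
  prod <- gate_product(c$gates)
  g_rhs <- if (is.null(prod)) ex_sym(c$gbar) else ex_bin("*", ex_sym(c$gbar), prod)
  i_rhs <- ex_bin("*", ex_sym(g_name),
                  ex_bin("-", ex_sym("v"), ex_sym(c$e_rev)))
  list(ent_assignment(g_name, g_rhs),
       ent_assignment(i_name, i_rhs),
       ent_assignment(pre(paste0("i_", c$name)), ex_sym(i_name)))
}

#' Assemble the equations of a GHK current
#'
#' `i_<name> = pmax * prod(gates^power) * ghk(v, ci, co, z, celsius)`; the
#' internal concentration may be an input-wired identifier (e.g. `cai`
#' from a decaying pool).
#'
#' @param c A [current_spec()] with `law = "GHK"`.
#' @param path Optional scope path for the generated names.
#' @return List of entities.
#' @export
assemble_ghk_current <- function(c, path = NULL) {
  stopifnot(inherits(c, "im_current_spec"))
  if (c$law != "GHK") validation_error("assemble_ghk_current: law must be GHK")
  pre <- prefix_names(path %||% character(0))
  i_name <- pre(paste0(c$name, "_i"))
  flux <- ex_app("ghk", list(ex_sym("v"), ex_sym(c$conc_in),
                             ex_sym(c$conc_out), ex_num(c$valence),
                             ex_sym("celsius")))
  prod <- gate_product(c$gates)
  base <- ex_bin("*", ex_sym(c$gbar), flux)
  i_rhs <- if (is.null(prod)) base else
    ex_bin("*", ex_bin("*", ex_sym(c$gbar), prod), flux)
  list(ent_assignment(i_name, i_rhs),
       ent_assignment(pre(paste0("i_", c$name)), ex_sym(i_name)))
}

## ------------------------------------------------------------ pools ----

#' Pool specification
#'
#' A decaying ion pool (Traub-style): the concentration relaxes to
#' `steady` with time constant `tau` and accumulates the named currents
#' scaled by the current-to-concentration factor `b`:
#' `d(conc)/dt = -b * sum(i_src) - (conc - steady) / tau`.
#'
#' @param name Pool (ion) name.
#' @param sources Names of the source current components.
#' @param exported Name of the exported concentration variable.
#' @param steady,tau,b Names of the pool parameters (defined as consts in
#'   the pool component).
#' @export
pool_spec <- function(name, sources, exported,
                      steady = "steady", tau = "tau", b = "b") {
  if (length(sources) < 1L) wiring_error(sprintf(
    "pool '%s' has no source currents", name))
  structure(list(name = name, sources = sources, exported = exported,
                 steady = steady, tau = tau, b = b),
            class = "im_pool_spec")
}

#' Expand a decaying pool into its concentration ODE
#'
#' @param p A [pool_spec()].
#' @param path Optional scope path for the generated names.
#' @return A RATE entity for the exported concentration.
#' @export
expand_decaying_pool <- function(p, path = NULL) {
  stopifnot(inherits(p, "im_pool_spec"))
  pre <- prefix_names(path %||% character(0))
  isum <- Reduce(function(a, b) ex_bin("+", a, b),
                 lapply(p$sources, function(s) ex_sym(paste0("i_", s))))
  conc <- pre(p$exported)
  rhs <- ex_bin("-",
    ex_neg(ex_bin("*", ex_sym(pre(p$b)), isum)),
    ex_bin("/", ex_bin("-", ex_sym(conc), ex_sym(pre(p$steady))),
           ex_sym(pre(p$tau))))
  ent_rate(conc, rhs)
}

## ------------------------------------------- membrane potential ----

#' Assemble the membrane-potential equation
#'
#' Sums every current of the model (Ohmic and GHK alike) into
#' `dv/dt = (i_stim - sum(i_<name>)) / C`, where `C` is the value exported
#' by the single membrane-capacitance component and `i_stim` is the
#' reserved applied-current symbol (0 unless a stimulus is supplied to the
#' integrator).
#'
#' @param model_env A flattened environment whose currents have been
#'   assembled (it must contain the `i_<name>` aliases and the capacitance
#'   component record).
#' @return A RATE entity for `v`.
#' @export
assemble_membrane_potential <- function(model_env) {
  recs <- model_env$meta$components
  caps <- Filter(function(r) identical(r$ctype, "Membrane-capacitance"), recs)
  if (length(caps) != 1L) {
    structural_error("model must contain exactly one membrane-capacitance component")
  }
  cap_ref <- caps[[1L]]$outputs_flat[[1L]]
  currents <- model_env$meta$currents
  if (is.null(currents) || length(currents) == 0L) {
    structural_error("model contains no current components")
  }
  isum <- Reduce(function(a, b) ex_bin("+", a, b),
                 lapply(currents, function(cu) ex_sym(cu$alias)))
  rhs <- ex_bin("/", ex_bin("-", ex_sym("i_stim"), isum), ex_sym(cap_ref))
  ent_rate("v", rhs)
}
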