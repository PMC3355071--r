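# Reference runtime: an interpreting right-hand side over the compiled
# system, a stiff-capable adaptive integrator (deSolve::lsoda), and
# steady-state initialization.

state_symbols <- function(sys) names(sys$state_index)

# Defs whose value never changes during integration: no transitive
# dependence on a state, time or the applied current.
static_def_names <- function(sys) {
  states <- state_symbols(sys)
  dyn_roots <- c(states, "t", "i_stim")
  static <- character(0)
  dynamic <- character(0)
  for (d in sys$ordered_defs) {
    fv <- free_vars(d$rhs)
    if (any(fv %in% dyn_roots) || any(fv %in% dynamic)) {
      dynamic <- c(dynamic, d$name)
    } else {
      static <- c(static, d$name)
    }
  }
  static
}

relation_closure <- function(rel, envir) {
  f <- function() NULL
  formals(f) <- stats::setNames(
    rep(list(quote(expr = )), length(rel$formals)), rel$formals)
  body(f) <- expr_to_lang(rel$rhs)
  environment(f) <- envir
  f
}

# Build the evaluation machinery for a compiled system: an environment
# holding parameters, relations (as closures) and the ghk helper, plus the
# quoted dynamic assignments and derivative expressions.
build_evaluator <- function(sys) {
  ev <- new.env(parent = baseenv())
  ev$ghk <- ghk_flux
  for (rel in sys$relations) {
    assign(rel$name, relation_closure(rel, ev), envir = ev)
  }
  statics <- static_def_names(sys)
  dynamic <- list()
  ev$t <- 0
  ev$i_stim <- 0
  for (s in state_symbols(sys)) assign(s, 0, envir = ev)
  for (d in sys$ordered_defs) {
    if (d$name %in% statics) {
      assign(d$name, eval(expr_to_lang(d$rhs), ev), envir = ev)
    } else {
      dynamic[[length(dynamic) + 1L]] <-
        list(name = d$name, lang = expr_to_lang(d$rhs))
    }
  }
  list(env = ev,
       dynamic = dynamic,
       ode_lang = lapply(sys$odes, function(o) expr_to_lang(o$rhs)),
       states = state_symbols(sys))
}

eval_dynamic <- function(ek) {
  for (d in ek$dynamic) assign(d$name, eval(d$lang, ek$env), envir = ek$env)
}

#' Steady-state initial values
#'
#' Builds the initial state vector at a holding potential `V0`: HH gates
#' are set to `alpha/(alpha + beta)` (equivalently `inf(V0)`), kinetic
#' scheme occupancies solve the linear steady-state system under the
#' conservation constraint, pool concentrations start at their resting
#' value, and `v = V0`.
#'
#' @param sys An `im_ode_system`.
#' @param V0 Initial membrane potential (mV).
#' @return Named numeric state vector in state-index order.
#' @export
steady_state_init <- function(sys, V0 = 0) {
  if (!is.finite(V0)) validation_error("V0 must be finite")
  ek <- build_evaluator(sys)
  ev <- ek$env
  ev$v <- V0
  eval_dynamic(ek)
  y0 <- stats::setNames(numeric(length(ek$states)), ek$states)
  if ("v" %in% ek$states) y0[["v"]] <- V0

  for (cu in sys$meta$currents %||% list()) {
    for (g in cu$gates) {
      val <- if (identical(g$form, "ab")) {
        a <- get(g$alpha, envir = ev)(V0)
        b <- get(g$beta, envir = ev)(V0)
        a / (a + b)
      } else {
        inf <- get(g$inf, envir = ev)
        if (is.function(inf)) inf(V0) else inf
      }
      y0[[g$state]] <- val
    }
  }

  for (rx in sys$reactions) {
    occ <- reaction_steady_state(rx, ev)
    for (s in names(occ)) y0[[s]] <- occ[[s]]
  }

  for (p in sys$meta$pools %||% list()) {
    if (p$exported %in% names(y0)) {
      y0[[p$exported]] <- get(p$steady, envir = ev)
    }
  }
  y0
}

# Solve M p = 0 with sum(p) = conserve for a kinetic scheme, rates
# evaluated in the given environment (v etc. already bound).
reaction_steady_state <- function(rx, ev) {
  states <- rx$states
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  for (tr in rx$transitions) {
    f <- eval(expr_to_lang(tr$fwd), ev)
    M[tr$dst, tr$src] <- M[tr$dst, tr$src] + f
    M[tr$src, tr$src] <- M[tr$src, tr$src] - f
    if (!is.null(tr$rev)) {
      r <- eval(expr_to_lang(tr$rev), ev)
      M[tr$src, tr$dst] <- M[tr$src, tr$dst] + r
      M[tr$dst, tr$dst] <- M[tr$dst, tr$dst] - r
    }
  }
  A <- rbind(M[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1L), rx$conserve)
  p <- tryCatch(solve(A, b), error = function(e) {
    im_error(sprintf("kinetic scheme '%s': singular steady-state system (%s)",
                     rx$name, conditionMessage(e)), "im_singular_error")
  })
  stats::setNames(as.numeric(p), states)
}

#' Integrate a compiled model
#'
#' Reference integrator over the interpreted right-hand side, using a
#' stiff-capable adaptive method (deSolve's `lsoda` by default) with
#' tolerances suited to stiff channel kinetics (rtol 1e-7, atol 1e-9).
#' Results are deterministic given inputs and tolerances.
#'
#' @param sys An `im_ode_system`, or an `im_model` (its system is used).
#' @param cfg A simulation configuration from [build_sim_config()]
#'   (duration/stepsize), or `NULL` if `duration` is given.
#' @param y0 Initial state vector; defaults to [steady_state_init()] at
#'   `v0`.
#' @param duration Simulated time (ms); overrides `cfg`.
#' @param stim Applied current density (uA/cm^2) added to the
#'   membrane-potential equation; default 0.
#' @param v0 Initial potential for the default initialization.
#' @param times Output time grid (ms); default: 2001 evenly spaced points
#'   (the reporting grid is decoupled from the solver's internal adaptive
#'   steps).
#' @param rtol,atol,method Integrator controls.
#' @param record_currents Add one column per model current to the output.
#' @return A data.frame: `time`, one column per state, and (optionally)
#'   one column per current.
#' @export
simulate_model <- function(sys, cfg = NULL, y0 = NULL, duration = NULL,
                           stim = 0, v0 = 0, times = NULL,
                           rtol = 1e-7, atol = 1e-9, method = "lsoda",
                           record_currents = TRUE) {
  if (inherits(sys, "im_model")) sys <- sys$sys
  if (is.null(duration)) {
    if (is.null(cfg)) validation_error("either cfg or duration is required")
    duration <- cfg$duration
  }
  if (is.null(times)) times <- seq(0, duration, length.out = 2001L)
  if (is.null(y0)) y0 <- steady_state_init(sys, v0)
  if (length(y0) != length(sys$state_index)) {
    validation_error(sprintf("y0 has %d entries but the system has %d states",
                             length(y0), length(sys$state_index)))
  }
  ek <- build_evaluator(sys)
  ev <- ek$env
  ev$i_stim <- stim
  states <- ek$states
  cur_names <- vapply(sys$meta$currents %||% list(),
                      function(cu) cu$alias, "")
  monitor <- record_currents && length(cur_names) > 0L
  func <- function(t, y, parms) {
    ev$t <- t
    for (i in seq_along(states)) assign(states[[i]], y[[i]], envir = ev)
    eval_dynamic(ek)
    dy <- vapply(ek$ode_lang, function(l) eval(l, ev), 0.0)
    if (monitor) {
      list(dy, vapply(cur_names, function(nm) get(nm, envir = ev), 0.0))
    } else {
      list(dy)
    }
  }
  out <- deSolve::ode(y = as.numeric(y0), times = times, func = func,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[[1L]] < 0) {
    im_error(sprintf("integration failed (istate = %d)",
                     attr(out, "istate")[[1L]]), "im_integration_error")
  }
  df <- as.data.frame(out)
  names(df) <- c("time", states, if (monitor) cur_names)
  class(df) <- c("im_trajectory", class(df))
  df
}

# Variant of a system with the membrane potential clamped: dv/dt = 0, all
# other equations untouched.
clamp_system <- function(sys) {
  sys$odes <- lapply(sys$odes, function(o) {
    if (identical(o$state, "v")) list(state = "v", rhs = ex_num(0)) else o
  })
  sys
}
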