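# Simulation and voltage-clamp experiment layer.

component_consts <- function(comp) {
  vals <- list()
  for (d in comp$decls) {
    ent <- build_entity(d)
    if (ent$kind %in% c("PARAMETER", "ASSIGNMENT") &&
        length(free_vars(ent$rhs)) == 0L) {
      vals[[ent$name]] <- eval_expr(ent$rhs)
    }
  }
  vals
}

require_const <- function(vals, name, where) {
  if (is.null(vals[[name]])) {
    grammar_error(sprintf("%s component is missing const '%s'", where, name))
  }
  vals[[name]]
}

#' Build a simulation configuration
#'
#' Reads `duration` and `stepsize` from a `simulation` component; all
#' fields are mandatory and must satisfy `0 < stepsize < duration`.
#'
#' @param c A ComponentDecl (or SyntaxNode / source text) of type
#'   `simulation`.
#' @return An `im_sim_config` list with `duration` and `stepsize` (ms).
#' @export
build_sim_config <- function(c) {
  c <- as_component(c)
  if (!identical(c$ctype, "simulation")) {
    validation_error("build_sim_config expects a simulation component")
  }
  vals <- component_consts(c)
  duration <- require_const(vals, "duration", "simulation")
  stepsize <- require_const(vals, "stepsize", "simulation")
  if (!(duration > 0) || !(stepsize > 0) || !(stepsize < duration)) {
    validation_error(sprintf(
      "simulation requires 0 < stepsize < duration (got stepsize = %g, duration = %g)",
      stepsize, duration))
  }
  structure(list(duration = duration, stepsize = stepsize),
            class = "im_sim_config")
}

#' Build a voltage-clamp protocol
#'
#' Reads the clamp parameters from a `voltage-clamp` component and checks
#' the semantic requirement that the model contains an ionic current
#' component of the same name.
#'
#' @param c A ComponentDecl (or SyntaxNode / source text) of type
#'   `voltage-clamp`.
#' @param model A lowered environment ([lower_model()]) or `im_model`
#'   providing the current components to validate against.
#' @return An `im_clamp_protocol` list.
#' @export
build_clamp_protocol <- function(c, model) {
  c <- as_component(c)
  if (!identical(c$ctype, "voltage-clamp")) {
    validation_error("build_clamp_protocol expects a voltage-clamp component")
  }
  if (is.na(c$cname)) {
    validation_error("voltage-clamp must name the clamped current")
  }
  env <- if (inherits(model, "im_model")) model$env else model
  currents <- env$meta$currents %||% list()
  hit <- Filter(function(cu) identical(cu$name, c$cname), currents)
  if (length(hit) == 0L) {
    im_error(sprintf(
      "voltage-clamp '%s': model has no ionic current component of that name",
      c$cname), "im_consistency_error")
  }
  vals <- component_consts(c)
  p <- structure(list(
    current = c$cname,
    alias = hit[[1L]]$alias,
    hold = require_const(vals, "hold", "voltage-clamp"),
    base = require_const(vals, "base", "voltage-clamp"),
    stepsize = require_const(vals, "stepsize", "voltage-clamp"),
    nsteps = as.integer(require_const(vals, "nsteps", "voltage-clamp")),
    holding_duration = require_const(vals, "holding-duration", "voltage-clamp"),
    base_duration = require_const(vals, "base-duration", "voltage-clamp")
  ), class = "im_clamp_protocol")
  if (p$nsteps < 1L) validation_error("voltage-clamp: nsteps must be >= 1")
  if (!(p$holding_duration > 0) || !(p$base_duration > 0)) {
    validation_error("voltage-clamp: durations must be positive")
  }
  p
}

#' Command voltages of a clamp protocol
#'
#' Steps ascend from `base` in increments of `stepsize`:
#' `base + k * stepsize` for `k = 0 ... nsteps - 1`.
#'
#' @param p An `im_clamp_protocol`.
#' @return Numeric vector of command voltages (mV).
#' @export
expand_clamp_steps <- function(p) {
  p$base + (seq_len(p$nsteps) - 1L) * p$stepsize
}

#' Run a voltage-clamp experiment with the reference integrator
#'
#' For each command voltage the membrane potential is held at `hold` for
#' `holding_duration` ms, then stepped to the command for `base_duration`
#' ms, with the membrane-potential equation replaced by a clamped one
#' (derivative identically zero within each phase); the named current is
#' recorded throughout. All non-voltage equations are untouched.
#'
#' @param model An `im_model` (from [compile_model()]).
#' @param p An `im_clamp_protocol`; defaults to the first protocol
#'   declared in the model.
#' @param points_per_phase Output samples per phase.
#' @param ... Passed to [simulate_model()] (tolerances etc.).
#' @return List with `protocol`, `commands`, and `sweeps` (one data frame
#'   per command: time, v, current).
#' @export
run_clamp <- function(model, p = NULL, points_per_phase = 400L, ...) {
  stopifnot(inherits(model, "im_model"))
  if (is.null(p)) {
    if (length(model$clamps) == 0L) {
      validation_error("model declares no voltage-clamp component")
    }
    p <- model$clamps[[1L]]
  }
  sys <- model$sys
  csys <- clamp_system(sys)
  commands <- expand_clamp_steps(p)
  vi <- sys$state_index[["v"]] + 1L
  sweeps <- lapply(commands, function(cmd) {
    y0 <- steady_state_init(sys, p$hold)
    t1 <- seq(0, p$holding_duration, length.out = points_per_phase)
    ph1 <- simulate_model(csys, y0 = y0, duration = p$holding_duration,
                          times = t1, ...)
    y1 <- as.numeric(ph1[nrow(ph1), 1L + seq_along(sys$state_index)])
    y1[vi] <- cmd
    t2 <- seq(0, p$base_duration, length.out = points_per_phase)
    ph2 <- simulate_model(csys, y0 = y1, duration = p$base_duration,
                          times = t2, ...)
    ph2$time <- ph2$time + p$holding_duration
    out <- rbind(ph1, ph2)
    data.frame(time = out$time, v = out$v, i = out[[p$alias]])
  })
  list(protocol = p, commands = commands, sweeps = sweeps)
}

#' Generate a voltage-clamp script
#'
#' Emits a self-contained script (R solver dialect or Octave/Matlab
#' dialect) that reproduces [run_clamp()]: the clamped variant of the
#' model (membrane-potential derivative replaced by zero), one sweep per
#' command voltage, recording the clamped current.
#'
#' @param p An `im_clamp_protocol`.
#' @param model An `im_model`.
#' @param target `"solver"` (R) or `"octave"`.
#' @return Script source text.
#' @export
generate_clamp_script <- function(p, model, target = c("solver", "octave")) {
  target <- match.arg(target)
  stopifnot(inherits(model, "im_model"))
  csys <- clamp_system(model$sys)
  commands <- expand_clamp_steps(p)
  vi <- model$sys$state_index[["v"]] + 1L
  if (target == "solver") {
    paste0(
      "# voltage-clamp script generated by ionmodl\n",
      "# current: ", p$current, "; one sweep per command voltage\n",
      "library(deSolve)\n",
      "bundle <- ", emit_solver_function(csys), "\n",
      "commands <- c(", paste(vapply(commands, fmt_number, ""),
                              collapse = ", "), ")\n",
      "hold <- ", fmt_number(p$hold), "\n",
      "holding_duration <- ", fmt_number(p$holding_duration), "\n",
      "base_duration <- ", fmt_number(p$base_duration), "\n",
      paste0(vapply(seq_along(commands), function(k) {
        sprintf("# sweep %d: command %s mV\n", k,
                fmt_number(commands[[k]]))
      }, ""), collapse = ""),
      "sweeps <- vector(\"list\", length(commands))\n",
      "for (k in seq_along(commands)) {\n",
      "  y0 <- bundle$init(hold)\n",
      "  f <- function(t, y, parms) list(bundle$rhs(t, y))\n",
      "  t1 <- seq(0, holding_duration, length.out = 200)\n",
      "  ph1 <- ode(y0, t1, f, NULL, method = \"lsoda\",",
      " rtol = 1e-7, atol = 1e-9)\n",
      "  y1 <- as.numeric(ph1[nrow(ph1), -1])\n",
      "  y1[", vi, "] <- commands[k]\n",
      "  t2 <- seq(0, base_duration, length.out = 400)\n",
      "  ph2 <- ode(y1, t2, f, NULL, method = \"lsoda\",",
      " rtol = 1e-7, atol = 1e-9)\n",
      "  i2 <- apply(ph2, 1, function(r) bundle$currents(r[1], r[-1])[\"",
      p$alias, "\"])\n",
      "  sweeps[[k]] <- data.frame(time = ph2[, 1] + holding_duration,",
      " i = as.numeric(i2))\n",
      "}\n")
  } else {
    paste0(
      "% voltage-clamp script generated by ionmodl\n",
      "% current: ", p$current, "; one sweep per command voltage\n",
      emit_octave_core(csys),
      "commands = [", paste(vapply(commands, fmt_number, ""),
                            collapse = ", "), "];\n",
      "hold_v = ", fmt_number(p$hold), ";\n",
      "holding_duration = ", fmt_number(p$holding_duration), ";\n",
      "base_duration = ", fmt_number(p$base_duration), ";\n",
      paste0(vapply(seq_along(commands), function(k) {
        sprintf("%% sweep %d: command %s mV\n", k,
                fmt_number(commands[[k]]))
      }, ""), collapse = ""),
      "sweeps = cell(1, length(commands));\n",
      "for k = 1:length(commands)\n",
      "  y0 = model_init(hold_v);\n",
      "  t1 = linspace(0, holding_duration, 200)';\n",
      "  y1 = lsode(@(y, t) model_rhs(t, y), y0, t1);\n",
      "  ystep = y1(end, :)';\n",
      "  ystep(", vi, ") = commands(k);\n",
      "  t2 = linspace(0, base_duration, 400)';\n",
      "  y2 = lsode(@(y, t) model_rhs(t, y), ystep, t2);\n",
      "  sweeps{k} = y2;\n",
      "end\n")
  }
}
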