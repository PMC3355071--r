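# Code emission: R solver-API target and Octave/Matlab script target.
# Emission is canonical (fixed ordering and formatting), so identical
# systems always produce byte-identical text.

uses_ghk <- function(sys) {
  any(vapply(sys$meta$currents %||% list(),
             function(cu) identical(cu$law, "GHK"), TRUE))
}

ghk_text_r <- function(indent = "  ") {
  paste0(indent, c(
    "ghk <- function(v, ci, co, z, celsius) {",
    "  u <- z * 96485.33212 * (v * 0.001) / (8.31446 * (celsius + 273.15))",
    "  if (abs(u) < 1e-6) {",
    "    z * 96485.33212 * ((ci - co) + u * (ci + co) / 2)",
    "  } else {",
    "    z * 96485.33212 * u * (ci - co * exp(-u)) / (1 - exp(-u))",
    "  }",
    "}"), collapse = "\n")
}

relation_lines_r <- function(sys, indent) {
  vapply(sys$relations, function(rel) {
    paste0(indent, rel$name, " <- function(",
           paste(rel$formals, collapse = ", "), ") ",
           expr_text(rel$rhs, "r"))
  }, "")
}

def_lines_r <- function(sys, indent) {
  vapply(sys$ordered_defs, function(d) {
    paste0(indent, d$name, " <- ", expr_text(d$rhs, "r"))
  }, "")
}

init_assignments <- function(sys) {
  # index (1-based) -> source text of the initial value, in a scope where
  # v0, the relations and all defs are available
  idx <- sys$state_index
  out <- list()
  for (cu in sys$meta$currents %||% list()) {
    for (g in cu$gates) {
      src <- if (identical(g$form, "ab")) {
        sprintf("%s(v0) / (%s(v0) + %s(v0))", g$alpha, g$alpha, g$beta)
      } else if (identical(g$inf_kind, "RELATION")) {
        sprintf("%s(v0)", g$inf)
      } else {
        g$inf
      }
      out[[g$state]] <- src
    }
  }
  for (rx in sys$reactions) {
    # uniform occupancies; the package-level steady_state_init solves the
    # full linear steady state instead
    for (s in rx$states) {
      out[[s]] <- fmt_number(rx$conserve / length(rx$states))
    }
  }
  for (p in sys$meta$pools %||% list()) {
    if (p$exported %in% names(idx)) out[[p$exported]] <- p$steady
  }
  out
}

#' Emit the solver-API right-hand side (R target)
#'
#' Generates self-contained R source text evaluating to a list with
#' `rhs(t, y, i_stim = 0)` (the derivative function, unpacking the state
#' vector through the state index), `init(v0)` (an initial-vector
#' constructor: HH gates at steady state, kinetic schemes at uniform
#' occupancy, pools at rest), `currents(t, y, i_stim = 0)` (named current
#' densities) and `states` (the state names in index order). Emission is
#' deterministic: byte-identical text for identical systems.
#'
#' @param sys An `im_ode_system`.
#' @return R source text (a single character string); `eval(parse(text =
#'   ...))` yields the bundle.
#' @export
emit_solver_function <- function(sys) {
  states <- names(sys$state_index)
  n <- length(states)
  unpack <- c("    y <- as.numeric(y)",
              vapply(seq_len(n), function(i) {
                sprintf("    %s <- y[%d]", states[[i]], i)
              }, ""))
  rels <- relation_lines_r(sys, "    ")
  defs <- def_lines_r(sys, "    ")
  dys <- vapply(seq_len(n), function(i) {
    sprintf("    dy[%d] <- %s", i, expr_text(sys$odes[[i]]$rhs, "r"))
  }, "")
  cur_names <- vapply(sys$meta$currents %||% list(),
                      function(cu) cu$alias, "")
  curvec <- if (length(cur_names) > 0L) {
    paste0("    c(", paste(sprintf("%s = %s", cur_names, cur_names),
                           collapse = ", "), ")")
  } else {
    "    numeric(0)"
  }
  inits <- init_assignments(sys)
  init_lines <- c(
    "    t <- 0",
    "    i_stim <- 0",
    "    v <- v0",
    vapply(setdiff(states, "v"), function(s) sprintf("    %s <- 0", s), ""),
    rels,
    defs,
    sprintf("    y0 <- numeric(%d)", n),
    vapply(seq_len(n), function(i) {
      s <- states[[i]]
      val <- if (identical(s, "v")) "v0" else inits[[s]] %||% "0"
      sprintf("    y0[%d] <- %s", i, val)
    }, ""),
    "    y0")

  body_common <- c(unpack, rels, defs)
  paste0(c(
    "# ODE system emitted by ionmodl",
    "local({",
    ghk_text_r("  "),
    "  rhs <- function(t, y, i_stim = 0) {",
    body_common,
    sprintf("    dy <- numeric(%d)", n),
    dys,
    "    dy",
    "  }",
    "  currents <- function(t, y, i_stim = 0) {",
    body_common,
    curvec,
    "  }",
    "  init <- function(v0 = 0) {",
    init_lines,
    "  }",
    paste0("  states <- c(",
           paste(sprintf("\"%s\"", states), collapse = ", "), ")"),
    "  list(rhs = rhs, init = init, currents = currents, states = states)",
    "})"
  ), collapse = "\n")
}

## ----------------------------------------------------- octave target ----

ghk_text_octave <- function() {
  paste(c(
    "function r = ghk(v, ci, co, z, celsius)",
    "  u = z * 96485.33212 * (v * 0.001) / (8.31446 * (celsius + 273.15));",
    "  if (abs(u) < 1e-6)",
    "    r = z * 96485.33212 * ((ci - co) + u * (ci + co) / 2);",
    "  else",
    "    r = z * 96485.33212 * u * (ci - co * exp(-u)) / (1 - exp(-u));",
    "  end",
    "end",
    ""), collapse = "\n")
}

octave_static_defs <- function(sys, indent) {
  statics <- static_def_names(sys)
  lines <- character(0)
  for (d in sys$ordered_defs) {
    if (d$name %in% statics) {
      lines <- c(lines, paste0(indent, d$name, " = ",
                               expr_text(d$rhs, "octave"), ";"))
    }
  }
  lines
}

# Core definitions shared by the full script and the clamp driver: ghk,
# one function per relation (constant parameters are inlined so the
# function bodies are self-contained), the right-hand side and the
# initial-vector constructor.
emit_octave_core <- function(sys) {
  states <- names(sys$state_index)
  n <- length(states)
  statics <- octave_static_defs(sys, "  ")
  rel_funs <- vapply(sys$relations, function(rel) {
    paste0("function r = ", rel$name, "(",
           paste(rel$formals, collapse = ", "), ")\n",
           paste(c(statics,
                   paste0("  r = ", expr_text(rel$rhs, "octave"), ";")),
                 collapse = "\n"),
           "\nend\n")
  }, "")
  unpack <- vapply(seq_len(n), function(i) {
    sprintf("  %s = y(%d);", states[[i]], i)
  }, "")
  defs <- vapply(sys$ordered_defs, function(d) {
    paste0("  ", d$name, " = ", expr_text(d$rhs, "octave"), ";")
  }, "")
  dys <- vapply(seq_len(n), function(i) {
    sprintf("  dy(%d) = %s;", i, expr_text(sys$odes[[i]]$rhs, "octave"))
  }, "")
  inits <- init_assignments(sys)
  init_lines <- c(
    "  t = 0;",
    "  i_stim = 0;",
    "  v = v0;",
    vapply(setdiff(states, "v"), function(s) sprintf("  %s = 0;", s), ""),
    defs,
    sprintf("  y0 = zeros(%d, 1);", n),
    vapply(seq_len(n), function(i) {
      s <- states[[i]]
      val <- if (identical(s, "v")) "v0" else octave_init_value(inits[[s]])
      sprintf("  y0(%d) = %s;", i, val)
    }, ""))
  paste0(
    "1;\n\n",
    ghk_text_octave(), "\n",
    paste(rel_funs, collapse = "\n"),
    "\nfunction dy = model_rhs(t, y)\n",
    "  i_stim = 0;\n",
    paste(unpack, collapse = "\n"), "\n",
    paste(defs, collapse = "\n"), "\n",
    sprintf("  dy = zeros(%d, 1);\n", n),
    paste(dys, collapse = "\n"), "\n",
    "end\n\n",
    "function y0 = model_init(v0)\n",
    paste(init_lines, collapse = "\n"), "\n",
    "  y0;\nend\n\n")
}

octave_init_value <- function(src) {
  if (is.null(src)) "0" else src
}

#' Emit a numeric-scripting (Octave/Matlab dialect) simulation script
#'
#' Generates a complete script: the constant-field helper, one function
#' per relation, the right-hand side `model_rhs(t, y)`, the initial-vector
#' constructor `model_init(v0)`, and a solver driver using the duration
#' and step size of the given simulation configuration. Emission is
#' deterministic.
#'
#' @param sys An `im_ode_system`.
#' @param cfg An `im_sim_config` from [build_sim_config()].
#' @return Script source text.
#' @export
emit_octave_script <- function(sys, cfg) {
  stopifnot(inherits(cfg, "im_sim_config"))
  paste0(
    "% ODE system emitted by ionmodl (Octave/Matlab dialect)\n",
    emit_octave_core(sys),
    "% simulation driver\n",
    "duration = ", fmt_number(cfg$duration), ";\n",
    "stepsize = ", fmt_number(cfg$stepsize), ";\n",
    "tout = (0:stepsize:duration)';\n",
    "y0 = model_init(0);\n",
    "y = lsode(@(y, t) model_rhs(t, y), y0, tout);\n")
}
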