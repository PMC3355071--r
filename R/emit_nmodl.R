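# NMODL (NEURON 7.x dialect) code generation, one mechanism per current
# (plus one per ion pool) or a single merged mechanism with collision-free
# path-prefixed names and per-species current summation.

nmodl_check_name <- function(nm) {
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", nm)) {
    im_error(sprintf("identifier '%s' is not legal in NMODL", nm),
             "im_naming_error")
  }
  nm
}

owned_by <- function(nm, prefixes) {
  any(vapply(prefixes, function(p) startsWith(nm, paste0(p, "_")), TRUE))
}

reaction_state_names <- function(sys) {
  unlist(lapply(sys$reactions, function(r) r$states)) %||% character(0)
}

# Wired exports (e.g. cai) whose source is one of the given pools.
pool_exports <- function(sys, pools) {
  out <- list()
  for (w in sys$meta$inputs %||% list()) {
    for (p in pools) {
      if (identical(w$src_ctype, "decaying-pool") &&
          identical(sanitize_segment(w$src_cname), p$prefix)) {
        out[[w$local]] <- p
      }
    }
  }
  out
}

nmodl_expr <- function(e) expr_text(e, "nmodl")

#' Emit NMODL mechanism files
#'
#' With `merge = FALSE`, one `.mod` file per ionic current (and one per
#' ion pool); with `merge = TRUE`, a single mechanism carrying all
#' equations under one SUFFIX, with per-species summation of the current
#' variables. Variable names are the collision-free path-prefixed names
#' produced by flattening, so merged and unmerged mechanisms contain the
#' same equations. HH-style gates are solved with `cnexp` DERIVATIVE
#' blocks, kinetic schemes with `sparse` KINETIC blocks (including a
#' CONSERVE statement); GHK currents emit a constant-field FUNCTION.
#'
#' @param sys An `im_ode_system`.
#' @param info An `im_model_info` from [build_model_info()].
#' @param merge Merge all mechanisms into a single file?
#' @return A named list of file texts (names are the `.mod` file names).
#' @export
emit_nmodl <- function(sys, info, merge = FALSE) {
  currents <- sys$meta$currents %||% list()
  pools <- sys$meta$pools %||% list()
  if (merge) {
    mechs <- list(list(suffix = sys$meta$model_name %||% "model",
                       currents = currents, pools = pools))
  } else {
    mechs <- c(
      lapply(currents, function(cu) {
        list(suffix = cu$prefix, currents = list(cu), pools = list())
      }),
      lapply(pools, function(p) {
        list(suffix = p$prefix, currents = list(), pools = list(p))
      })
    )
  }
  out <- lapply(mechs, function(m) emit_mechanism(sys, info, m, merge))
  stats::setNames(out, vapply(mechs, function(m) {
    paste0(nmodl_check_name(sanitize_segment(m$suffix)), ".mod")
  }, ""))
}

emit_mechanism <- function(sys, info, mech, merge) {
  prefixes <- c(vapply(mech$currents, function(cu) cu$prefix, ""),
                vapply(mech$pools, function(p) p$prefix, ""))
  rstates <- reaction_state_names(sys)
  exports <- pool_exports(sys, mech$pools)

  params <- Filter(function(d) d$kind == "PARAMETER" &&
                     owned_by(d$name, prefixes), sys$ordered_defs)
  assigns <- Filter(function(d) d$kind == "ASSIGNMENT" &&
                      (owned_by(d$name, prefixes) ||
                         d$name %in% names(exports)), sys$ordered_defs)
  rels <- Filter(function(r) owned_by(r$name, prefixes), sys$relations)
  reactions <- Filter(function(r) owned_by(r$name, prefixes), sys$reactions)
  hh_states <- Filter(function(o) {
    !identical(o$state, "v") && !o$state %in% rstates &&
      owned_by(o$state, prefixes)
  }, sys$odes)

  # In a standalone pool mechanism the source currents arrive through the
  # summed species current (READ ica); in a merged mechanism the internal
  # per-current variables are used directly.
  pool_subst <- list()
  for (p in mech$pools) {
    for (s in p$sources) {
      pool_subst[[paste0("i_", sanitize_segment(s))]] <-
        if (merge) ex_sym(paste0(sanitize_segment(s), "_i"))
        else ex_sym(paste0("i", p$ion))
    }
  }
  fix <- function(e) if (length(pool_subst)) subst(e, pool_subst) else e

  for (nm in c(vapply(params, function(d) d$name, ""),
               vapply(assigns, function(d) d$name, ""),
               vapply(hh_states, function(o) o$state, ""),
               rstates[rstates %in% unlist(lapply(reactions,
                                                  function(r) r$states))])) {
    nmodl_check_name(nm)
  }

  irecs <- Filter(function(r) r$current %in%
                    vapply(mech$currents, function(cu) cu$name, ""),
                  unclass(info))
  specific <- Filter(function(r) !identical(r$ion, "non-specific"), irecs)
  nonspecific <- Filter(function(r) identical(r$ion, "non-specific"), irecs)

  use_ion <- character(0)
  for (sp in unique(vapply(specific, function(r) r$ion, ""))) {
    rs <- Filter(function(r) identical(r$ion, sp), specific)
    reads <- character(0)
    ghk_here <- any(vapply(rs, function(r) identical(r$law, "GHK"), TRUE))
    if (any(vapply(rs, function(r) !is.na(r$reversal), TRUE))) {
      reads <- c(reads, paste0("e", sp))
    }
    if (ghk_here && !merge) reads <- c(reads, paste0(sp, "i"))
    val <- unique(unlist(lapply(mech$currents, function(cu) {
      if (identical(cu$ion, sp) && !is.na(cu$valence)) cu$valence else NULL
    })))
    use_ion <- c(use_ion, paste0(
      "  USEION ", sp,
      if (length(reads)) paste0(" READ ", paste(reads, collapse = ", ")),
      " WRITE i", sp,
      if (length(val) == 1L) paste0(" VALENCE ", val)))
  }
  for (p in mech$pools) {
    use_ion <- c(use_ion, paste0(
      "  USEION ", p$ion,
      if (!merge) paste0(" READ i", p$ion),
      " WRITE ", p$ion, "i"))
  }

  ranges <- setdiff(c(vapply(params, function(d) d$name, ""),
                      vapply(assigns, function(d) d$name, "")),
                    names(exports))
  # NONSPECIFIC_CURRENT declares the per-current variable itself
  ns_vars <- vapply(nonspecific, function(r) {
    cu <- Filter(function(c2) identical(c2$name, r$current),
                 mech$currents)[[1L]]
    cu$i_name
  }, "")
  neuron_block <- c(
    "NEURON {",
    paste0("  SUFFIX ", sanitize_segment(mech$suffix)),
    use_ion,
    if (length(ns_vars)) paste0("  NONSPECIFIC_CURRENT ",
                                paste(ns_vars, collapse = ", ")),
    if (length(ranges)) paste0("  RANGE ", paste(ranges, collapse = ", ")),
    "}")

  units_block <- c("UNITS {",
                   "  (mA) = (milliamp)",
                   "  (mV) = (millivolt)",
                   "  (mS) = (millisiemens)",
                   "  (mM) = (milli/liter)",
                   "}")

  param_block <- if (length(params)) {
    c("PARAMETER {",
      vapply(params, function(d) {
        paste0("  ", d$name, " = ", fmt_number(eval_expr(d$rhs)))
      }, ""),
      "}")
  }

  state_names <- c(vapply(hh_states, function(o) o$state, ""),
                   unlist(lapply(reactions, function(r) r$states)) %||%
                     character(0))
  state_block <- if (length(state_names)) {
    c("STATE {", paste0("  ", state_names), "}")
  }

  species_assigned <- unlist(lapply(irecs, function(r) {
    c(if (!is.na(r$reversal)) paste0("  ", r$reversal, " (mV)"),
      if (!is.na(r$ion_current)) paste0("  ", r$ion_current, " (mA/cm2)"),
      if (identical(r$law, "GHK") && !merge) paste0("  ", r$ion, "i (mM)"))
  })) %||% character(0)
  for (p in mech$pools) {
    species_assigned <- c(species_assigned,
                          if (!merge) paste0("  i", p$ion, " (mA/cm2)"),
                          paste0("  ", p$ion, "i (mM)"))
  }
  species_names <- sub("^\\s+", "", sub(" \\(.*$", "", species_assigned))
  assigned_block <- c(
    "ASSIGNED {",
    "  v (mV)",
    "  celsius (degC)",
    unique(species_assigned),
    unlist(lapply(assigns, function(d) {
      if (d$name %in% species_names) NULL else paste0("  ", d$name)
    })),
    "}")

  initial_block <- nmodl_initial(sys, mech, reactions)

  solve_lines <- c(
    if (length(hh_states)) "  SOLVE states METHOD cnexp",
    vapply(reactions, function(r) {
      paste0("  SOLVE ", r$name, " METHOD sparse")
    }, ""))
  assign_lines <- vapply(assigns, function(d) {
    paste0("  ", d$name, " = ", nmodl_expr(fix(d$rhs)))
  }, "")
  accum_lines <- character(0)
  for (sp in unique(vapply(specific, function(r) r$ion, ""))) {
    rs <- Filter(function(r) identical(r$ion, sp), specific)
    terms <- vapply(rs, function(r) {
      cu <- Filter(function(c2) identical(c2$name, r$current),
                   mech$currents)[[1L]]
      cu$i_name
    }, "")
    accum_lines <- c(accum_lines,
                     paste0("  i", sp, " = ", paste(terms, collapse = " + ")))
  }
  breakpoint_block <- c("BREAKPOINT {", solve_lines, assign_lines,
                        accum_lines, "}")

  derivative_block <- if (length(hh_states)) {
    c("DERIVATIVE states {",
      vapply(hh_states, function(o) {
        paste0("  ", o$state, "' = ", nmodl_expr(fix(o$rhs)))
      }, ""),
      "}")
  }

  kinetic_blocks <- unlist(lapply(reactions, function(r) {
    lines <- vapply(r$transitions, function(tr) {
      paste0("  ~ ", tr$src, " <-> ", tr$dst, " (", nmodl_expr(tr$fwd),
             ", ", if (is.null(tr$rev)) "0" else nmodl_expr(tr$rev), ")")
    }, "")
    c(paste0("KINETIC ", r$name, " {"),
      lines,
      paste0("  CONSERVE ", paste(r$states, collapse = " + "), " = ",
             fmt_number(r$conserve)),
      "}")
  })) %||% character(0)

  fun_blocks <- unlist(lapply(rels, function(rel) {
    c(paste0("FUNCTION ", rel$name, "(",
             paste(rel$formals, collapse = ", "), ") {"),
      paste0("  ", rel$name, " = ", nmodl_expr(rel$rhs)),
      "}")
  })) %||% character(0)
  if (any(vapply(mech$currents, function(cu) identical(cu$law, "GHK"),
                 TRUE))) {
    fun_blocks <- c(fun_blocks, nmodl_ghk_function())
  }

  blocks <- list(
    c(": mechanism generated by ionmodl", ""),
    neuron_block, units_block, param_block, state_block, assigned_block,
    initial_block, breakpoint_block, derivative_block)
  txt <- character(0)
  for (b in blocks) if (!is.null(b)) txt <- c(txt, b, "")
  if (length(kinetic_blocks)) txt <- c(txt, kinetic_blocks, "")
  if (length(fun_blocks)) txt <- c(txt, fun_blocks, "")
  paste0(paste(txt, collapse = "\n"), "\n")
}

nmodl_initial <- function(sys, mech, reactions) {
  lines <- character(0)
  for (cu in mech$currents) {
    for (g in cu$gates %||% list()) {
      src <- if (identical(g$form, "ab")) {
        sprintf("%s(v) / (%s(v) + %s(v))", g$alpha, g$alpha, g$beta)
      } else if (identical(g$inf_kind, "RELATION")) {
        sprintf("%s(v)", g$inf)
      } else {
        g$inf
      }
      lines <- c(lines, paste0("  ", g$state, " = ", src))
    }
  }
  for (r in reactions) {
    lines <- c(lines, paste0("  SOLVE ", r$name, " STEADYSTATE sparse"))
  }
  for (p in mech$pools) {
    lines <- c(lines, paste0("  ", p$exported, " = ", p$steady))
  }
  if (!length(lines)) return(NULL)
  c("INITIAL {", lines, "}")
}

nmodl_ghk_function <- function() {
  c("FUNCTION ghk(v, ci, co, z, temp) {",
    "  LOCAL u",
    "  u = z * 96485.33212 * (v * 0.001) / (8.31446 * (temp + 273.15))",
    "  if (fabs(u) < 1e-6) {",
    "    ghk = z * 96485.33212 * ((ci - co) + u * (ci + co) / 2)",
    "  } else {",
    "    ghk = z * 96485.33212 * u * (ci - co * exp(-u)) / (1 - exp(-u))",
    "  }",
    "}")
}

## ------------------------------------------ minimal NMODL reader ----

nmodl_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[[i]]
    m <- regmatches(ln, regexec(
      "^\\s*(NEURON|UNITS|PARAMETER|STATE|ASSIGNED|INITIAL|BREAKPOINT|DERIVATIVE|KINETIC|FUNCTION)\\b\\s*([A-Za-z0-9_]*)", ln))[[1L]]
    if (length(m) == 3L && nzchar(m[[2L]])) {
      depth <- 0L
      body <- character(0)
      repeat {
        depth <- depth + lengths(regmatches(lines[[i]],
                                            gregexpr("\\{", lines[[i]])))
        depth <- depth - lengths(regmatches(lines[[i]],
                                            gregexpr("\\}", lines[[i]])))
        body <- c(body, lines[[i]])
        i <- i + 1L
        if (depth <= 0L || i > n) break
      }
      blocks[[length(blocks) + 1L]] <-
        list(kind = m[[2L]], name = m[[3L]], body = body)
    } else {
      i <- i + 1L
    }
  }
  blocks
}

norm_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

#' Read the equation set of an NMODL mechanism
#'
#' Minimal reader used to compare merged and unmerged mechanism files: it
#' extracts parameter values, BREAKPOINT assignments, DERIVATIVE
#' equations, KINETIC reaction and CONSERVE statements, and FUNCTION
#' definitions as whitespace-normalized strings. SUFFIX/SOLVE plumbing is
#' ignored.
#'
#' @param text NMODL file text.
#' @return Sorted character vector of normalized equation strings.
#' @export
read_nmodl_equations <- function(text) {
  eqs <- character(0)
  for (b in nmodl_blocks(text)) {
    body <- b$body
    inner <- body[-c(1L, length(body))]
    inner <- inner[nzchar(trimws(inner))]
    if (b$kind == "PARAMETER") {
      eqs <- c(eqs, norm_ws(inner))
    } else if (b$kind == "BREAKPOINT") {
      keep <- inner[!grepl("^\\s*SOLVE\\b", inner)]
      eqs <- c(eqs, norm_ws(keep))
    } else if (b$kind %in% c("DERIVATIVE", "KINETIC")) {
      eqs <- c(eqs, norm_ws(inner))
    } else if (b$kind == "FUNCTION") {
      hdr <- norm_ws(sub("\\{\\s*$", "", body[[1L]]))
      eqs <- c(eqs, paste0(hdr, " :: ",
                           paste(norm_ws(inner), collapse = " ; ")))
    }
  }
  sort(eqs)
}

# All identifiers declared by a mechanism (used to check merge produces no
# duplicates).
nmodl_declared_names <- function(text) {
  out <- character(0)
  for (b in nmodl_blocks(text)) {
    body <- b$body
    inner <- body[-c(1L, length(body))]
    inner <- inner[nzchar(trimws(inner))]
    if (b$kind == "PARAMETER") {
      out <- c(out, sub("\\s*=.*$", "", trimws(inner)))
    } else if (b$kind == "STATE") {
      out <- c(out, unlist(strsplit(trimws(inner), "[[:space:]]+")))
    } else if (b$kind == "FUNCTION") {
      out <- c(out, sub("^FUNCTION\\s+([A-Za-z0-9_]+).*$", "\\1",
                        trimws(body[[1L]])))
    } else if (b$kind == "ASSIGNED") {
      out <- c(out, sub("\\s.*$", "", trimws(inner)))
    }
  }
  out
}
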