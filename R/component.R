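# Component layer: typed, named, output-declaring components with nesting,
# input wiring across components, and flattening to a single namespace.

.component_types <- c("Membrane-potential", "Membrane-capacitance",
                      "Ohmic-current", "gating", "hh-gating-dynamics",
                      "pore", "permeability", "permeating-ion",
                      "decaying-pool", "simulation", "voltage-clamp")

# Identifiers that cross component boundaries by construction and are never
# path-prefixed: membrane potential, time, temperature, applied current.
.reserved_globals <- c("v", "V", "t", "celsius", "i_stim")

.decl_heads <- c("const", "fun", "d", "reaction")

structural_error <- function(msg) im_error(msg, "im_structural_error")
wiring_error <- function(msg) im_error(msg, "im_wiring_error")

## ------------------------------------------------- component parsing ----

is_assignment_shape <- function(x) {
  is_node(x) && length(x$children) >= 3L && is_sym(x$children[[1L]]) &&
    is_op_atom(x$children[[2L]], "=")
}

#' Parse a syntax tree into a component declaration
#'
#' Components are `(<type> <name?> (out ...)? <declarations and nested
#' components> ...)`. The name may be a bare identifier after the type or a
#' `(name x)` clause. `(input (local from <type> <name> [output]))` clauses
#' wire values exported by other components into this one's scope.
#'
#' @param node A SyntaxNode whose head is a component type.
#' @return A ComponentDecl object.
#' @export
parse_component <- function(node) {
  head <- node_head(node)
  if (is.na(head) || !head %in% .component_types) {
    grammar_error(sprintf("unknown component type '%s'",
                          if (is.na(head)) "<non-symbol>" else head))
  }
  comp <- structure(list(ctype = head, cname = NA_character_,
                         outputs = character(0), inputs = list(),
                         decls = list(), children = list(),
                         clauses = list()),
                    class = "im_component")
  args <- node_args(node)
  i <- 1L
  if (length(args) >= 1L && is_sym(args[[1L]])) {
    comp$cname <- args[[1L]]$name
    i <- 2L
  }
  while (i <= length(args)) {
    item <- args[[i]]
    i <- i + 1L
    if (is_num_atom(item)) {            # compact value, e.g. capacitance
      comp$clauses[[length(comp$clauses) + 1L]] <- item
      next
    }
    if (!is_node(item)) {
      grammar_error(sprintf("unexpected token in component '%s'",
                            comp$ctype))
    }
    h <- node_head(item)
    if (identical(h, "name")) {
      comp$cname <- item$children[[2L]]$name
    } else if (!is.na(h) && h %in% c("out", "output")) {
      comp$outputs <- c(comp$outputs, vapply(node_args(item), function(a) {
        if (!is_sym(a)) grammar_error("out clause must list identifiers")
        a$name
      }, ""))
    } else if (identical(h, "input")) {
      for (w in node_args(item)) {
        comp$inputs[[length(comp$inputs) + 1L]] <- parse_input_decl(w)
      }
    } else if (!is.na(h) && h %in% .component_types) {
      comp$children[[length(comp$children) + 1L]] <- parse_component(item)
    } else if ((!is.na(h) && h %in% .decl_heads) || is_assignment_shape(item)) {
      comp$decls[[length(comp$decls) + 1L]] <- item
    } else {
      comp$clauses[[length(comp$clauses) + 1L]] <- item
    }
  }
  comp
}

parse_input_decl <- function(w) {
  if (!is_node(w)) grammar_error("input declaration must be (local from type name)")
  ch <- w$children
  if (length(ch) < 4L || !is_sym(ch[[1L]]) || !is_sym(ch[[2L]], "from") ||
      !is_sym(ch[[3L]]) || !is_sym(ch[[4L]])) {
    grammar_error("input declaration must be (local from <component-type> <component-name> [output])")
  }
  list(local = ch[[1L]]$name, src_ctype = ch[[3L]]$name,
       src_cname = ch[[4L]]$name,
       output = if (length(ch) >= 5L && is_sym(ch[[5L]])) ch[[5L]]$name
                else NA_character_)
}

## ------------------------------------------- structural validation ----

children_of_type <- function(comp, type) {
  Filter(function(c) identical(c$ctype, type), comp$children)
}

decl_named <- function(comp, name) {
  for (d in comp$decls) {
    nm <- if (identical(node_head(d), "const")) {
      d$children[[2L]]$name
    } else if (is_assignment_shape(d)) {
      d$children[[1L]]$name
    } else {
      NA_character_
    }
    if (identical(nm, name)) return(d)
  }
  NULL
}

# The structuring rules for ionic-current models: one membrane-capacitance
# component, one or more current components; each current carries exactly
# one conductance source (a pore, a permeability, or a compact g_max
# parameter) and one reversal/species source (a permeating-ion component or
# a compact E parameter). Gating subcomponents are optional: the canonical
# Hodgkin-Huxley formulation contains an ungated Leak current, so an empty
# gate product (= 1) is accepted.
validate_model_structure <- function(root) {
  if (!identical(root$ctype, "Membrane-potential")) {
    structural_error("model root must be a Membrane-potential component")
  }
  caps <- children_of_type(root, "Membrane-capacitance")
  if (length(caps) != 1L) {
    structural_error(sprintf(
      "model must contain exactly one membrane-capacitance component (found %d)",
      length(caps)))
  }
  currents <- children_of_type(root, "Ohmic-current")
  if (length(currents) < 1L) {
    structural_error("model must contain at least one current component")
  }
  for (cur in currents) validate_current_structure(cur)
  bad <- Filter(function(c) c$ctype %in% c("gating", "hh-gating-dynamics",
                                           "pore", "permeability",
                                           "permeating-ion"),
                root$children)
  if (length(bad) > 0L) {
    structural_error(sprintf(
      "component of type '%s' cannot appear at model top level",
      bad[[1L]]$ctype))
  }
  invisible(root)
}

validate_current_structure <- function(cur) {
  nm <- if (is.na(cur$cname)) "<unnamed>" else cur$cname
  if (is.na(cur$cname)) {
    structural_error("current components must be named")
  }
  pores <- children_of_type(cur, "pore")
  perms <- children_of_type(cur, "permeability")
  ions <- children_of_type(cur, "permeating-ion")
  has_gmax <- !is.null(decl_named(cur, "g_max"))
  n_cond <- length(pores) + length(perms) + as.integer(has_gmax)
  if (n_cond != 1L) {
    structural_error(sprintf(
      "current '%s' must have exactly one conductance source (pore, permeability or g_max); found %d",
      nm, n_cond))
  }
  if (length(ions) > 1L) {
    structural_error(sprintf(
      "current '%s' has multiple permeating-ion components", nm))
  }
  if (length(perms) == 1L) {
    if (length(ions) != 1L) {
      structural_error(sprintf(
        "GHK current '%s' requires a permeating-ion component with valence and concentrations",
        nm))
    }
  } else {
    has_e <- !is.null(decl_named(cur, "E")) ||
      (length(ions) == 1L && length(ions[[1L]]$outputs) >= 1L)
    if (!has_e) {
      structural_error(sprintf(
        "current '%s' has no reversal potential (permeating-ion output or E parameter)",
        nm))
    }
  }
  for (g in children_of_type(cur, "gating")) {
    if (is.na(g$cname)) {
      structural_error(sprintf("gating component in current '%s' must be named",
                               nm))
    }
  }
}

## ----------------------------------------------- nested environments ----

# Normalize the membrane-potential symbol: the listings use V, the lowered
# equations use v.
normalize_voltage <- function(e, skip = character(0)) {
  subst(e, list(V = ex_sym("v")), skip = skip)
}

normalize_entity <- function(ent) {
  if (ent$kind %in% c("PARAMETER", "ASSIGNMENT", "RATE")) {
    ent$rhs <- normalize_voltage(ent$rhs)
  } else if (ent$kind == "RELATION") {
    ent$rhs <- normalize_voltage(ent$rhs, skip = ent$formals)
  } else if (ent$kind == "REACTION") {
    ent$transitions <- lapply(ent$transitions, function(tr) {
      tr$fwd <- normalize_voltage(tr$fwd)
      if (!is.null(tr$rev)) tr$rev <- normalize_voltage(tr$rev)
      tr
    })
  }
  ent
}

add_entity <- function(env, ent) {
  ent <- normalize_entity(ent)
  # A literal algebraic equation, e.g. the compact (E = 115 mV), is a
  # constant during integration: treat it as a parameter.
  if (ent$kind == "ASSIGNMENT" && length(free_vars(ent$rhs)) == 0L &&
      length(applied_relations(ent$rhs)) == 0L) {
    ent <- ent_parameter(ent$name, ent$rhs)
  }
  extend_env(env, ent)
}

clause_named <- function(comp, head) {
  for (cl in comp$clauses) {
    if (is_node(cl) && identical(node_head(cl), head)) return(cl)
  }
  NULL
}

clause_value <- function(comp, head) {
  cl <- clause_named(comp, head)
  if (is.null(cl)) return(NA_real_)
  eval_expr(parse_expr_items(node_args(cl)))
}

#' Build the nested environment for a component
#'
#' Transforms the component syntax into nested environments mirroring the
#' component tree; each environment carries the component type, name and
#' declared outputs. Type-specific expansion happens here: gating
#' declarations become rate equations and rate relations, templates are
#' checked for their required entity names, decaying pools become the
#' concentration ODE. An output that does not name an entity defined in the
#' component is an error.
#'
#' @param comp A ComponentDecl from [parse_component()].
#' @return A nested environment.
#' @export
build_component_env <- function(comp) {
  env <- env_new(comp$ctype, comp$cname, comp$outputs)
  env$inputs <- comp$inputs
  env$meta <- list()
  builder <- switch(comp$ctype,
    "gating" = build_gating_env,
    "hh-gating-dynamics" = build_template_env,
    "decaying-pool" = build_pool_env,
    "Membrane-capacitance" = build_capacitance_env,
    "permeating-ion" = build_ion_env,
    build_generic_env
  )
  env <- builder(env, comp)
  for (child in comp$children) {
    cenv <- build_component_env(child)
    if (identical(comp$ctype, "Ohmic-current") &&
        child$ctype %in% c("gating", "hh-gating-dynamics")) {
      # Gate equations live in the current's own namespace so the lowered
      # names read like the conventional m_Na / alpha_m_Na after flattening.
      for (nm in env_names(cenv)) {
        env <- extend_env(env, cenv$entries[[nm]], name = nm)
      }
      env$meta$gates <- c(env$meta$gates, list(cenv$meta$gate))
    } else {
      env <- extend_env(env, cenv)
    }
  }
  missing <- setdiff(env$outputs, env_names(env))
  if (length(missing) > 0L) {
    im_error(sprintf(
      "component '%s' declares output '%s' which is not defined in its body",
      if (is.na(comp$cname)) comp$ctype else comp$cname, missing[[1L]]),
      "im_output_error")
  }
  env
}

build_generic_env <- function(env, comp) {
  for (d in comp$decls) env <- add_entity(env, build_entity(d))
  if (identical(comp$ctype, "Ohmic-current")) {
    for (cl in comp$clauses) {
      grammar_error(sprintf("unknown clause '%s' in current '%s'",
                            node_head(cl), comp$cname))
    }
  }
  env
}

build_capacitance_env <- function(env, comp) {
  for (d in comp$decls) env <- add_entity(env, build_entity(d))
  for (cl in comp$clauses) {
    if (is_num_atom(cl)) {   # compact form: (Membrane-capacitance 1.0 uF/cm*cm)
      env <- add_entity(env, ent_parameter("C", ex_num(cl$value), cl$unit))
    } else {
      grammar_error(sprintf("unknown clause '%s' in Membrane-capacitance",
                            node_head(cl)))
    }
  }
  if (length(env$outputs) == 0L) {
    cands <- env_names(env)
    if (length(cands) != 1L) {
      structural_error("Membrane-capacitance must export exactly one value")
    }
    env$outputs <- cands
  }
  env
}

build_ion_env <- function(env, comp) {
  for (d in comp$decls) env <- add_entity(env, build_entity(d))
  env$meta$ion <- comp$cname
  v <- clause_value(comp, "valence")
  env$meta$valence <- if (is.na(v)) NA_integer_ else as.integer(v)
  env
}

build_gating_env <- function(env, comp) {
  power <- clause_value(comp, "power")
  if (is.na(power)) power <- 1
  fwd <- clause_named(comp, "forward-rate")
  rev <- clause_named(comp, "reverse-rate")
  if (is.null(fwd) || is.null(rev)) {
    grammar_error(sprintf(
      "gating '%s' needs forward-rate and reverse-rate clauses", comp$cname))
  }
  spec <- gate_spec(comp$cname, power,
                    forward = parse_expr_items(node_args(fwd)),
                    reverse = parse_expr_items(node_args(rev)))
  for (ent in expand_hh_gating(spec)) env <- add_entity(env, ent)
  for (d in comp$decls) env <- add_entity(env, build_entity(d))
  if (length(env$outputs) == 0L) env$outputs <- comp$cname
  env$meta$gate <- list(state = comp$cname, power = spec$power, form = "ab",
                        alpha = paste0("alpha_", comp$cname),
                        beta = paste0("beta_", comp$cname))
  env
}

# HH-gating-dynamics template: a component whose contained equations are
# required to be named exactly <gate>_inf and tau_<gate>.
build_template_env <- function(env, comp) {
  if (is.na(comp$cname)) grammar_error("hh-gating-dynamics must name its gate")
  g <- comp$cname
  power <- clause_value(comp, "power")
  if (is.na(power)) power <- 1
  for (d in comp$decls) env <- add_entity(env, build_entity(d))
  inf_name <- paste0(g, "_inf")
  tau_name <- paste0("tau_", g)
  for (req in c(inf_name, tau_name)) {
    if (is.null(env_get(env, req))) {
      im_error(sprintf(
        "HH-gating-dynamics '%s' must contain an equation called exactly '%s'",
        g, req), "im_template_error")
    }
  }
  ref <- function(nm) {
    ent <- env_get(env, nm)
    if (ent$kind == "RELATION") ex_app(nm, list(ex_sym("v"))) else ex_sym(nm)
  }
  spec <- gate_spec(g, power, inf = ref(inf_name), tau = ref(tau_name))
  for (ent in expand_hh_gating(spec)) env <- add_entity(env, ent)
  if (length(env$outputs) == 0L) env$outputs <- g
  env$meta$gate <- list(state = g, power = spec$power, form = "it",
                        inf = inf_name, tau = tau_name,
                        inf_kind = env_get(env, inf_name)$kind,
                        tau_kind = env_get(env, tau_name)$kind)
  env
}

build_pool_env <- function(env, comp) {
  for (d in comp$decls) env <- add_entity(env, build_entity(d))
  sources <- character(0)
  for (cl in comp$clauses) {
    if (identical(node_head(cl), "current")) {
      sources <- c(sources, vapply(node_args(cl), function(a) a$name, ""))
    } else {
      grammar_error(sprintf("unknown clause '%s' in decaying-pool",
                            node_head(cl)))
    }
  }
  if (length(sources) == 0L) {
    wiring_error(sprintf("decaying-pool '%s' names no source currents",
                         comp$cname))
  }
  if (length(env$outputs) != 1L) {
    structural_error(sprintf(
      "decaying-pool '%s' must export exactly one concentration", comp$cname))
  }
  for (req in c("steady", "tau", "b")) {
    if (is.null(env_get(env, req))) {
      grammar_error(sprintf("decaying-pool '%s' must define const '%s'",
                            comp$cname, req))
    }
  }
  tau_ent <- env_get(env, "tau")
  if (tau_ent$kind == "PARAMETER" && eval_expr(tau_ent$rhs) <= 0) {
    im_error(sprintf("decaying-pool '%s': tau must be positive", comp$cname),
             "im_validation_error")
  }
  spec <- pool_spec(comp$cname, sources, exported = env$outputs[[1L]])
  env <- add_entity(env, expand_decaying_pool(spec))
  # Current values are wired in from the named current components after
  # flattening; register the placeholder names so they are not mangled.
  for (s in sources) {
    env$inputs[[length(env$inputs) + 1L]] <-
      list(local = paste0("i_", s), src_ctype = "Ohmic-current",
           src_cname = s, output = "i")
  }
  env$meta$pool <- list(name = comp$cname, sources = sources,
                        exported = env$outputs[[1L]])
  env
}

## ------------------------------------------------------- flattening ----

sanitize_segment <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

path_segment <- function(env) {
  sanitize_segment(if (!is.na(env$cname)) env$cname else env$ctype)
}

#' Flatten nested environments into a single namespace
#'
#' Every entity name is prefixed by its scope path (component names from
#' root to the defining component, joined with `_`); every expression is
#' rewritten so that all references point at the flattened names. An
#' identifier that is not defined in any enclosing scope and is not a
#' reserved global (`v`, `t`, `celsius`, `i_stim`) or a wired input is an
#' unresolved-reference error; two entities mapping to the same flattened
#' name is a collision error.
#'
#' @param env A nested environment from [build_component_env()].
#' @return A flat environment; `$meta$components` holds one record per
#'   component (type, name, prefix, flattened outputs, expansion metadata)
#'   and `$meta$inputs` the collected input wiring declarations.
#' @export
flatten <- function(env) {
  flat <- env_new(env$ctype, env$cname, character(0))
  records <- list()
  wiring <- list()
  flat_names_seen <- character(0)

  add_flat <- function(ent) {
    if (ent$name %in% flat_names_seen) {
      im_error(sprintf("flattening collision: duplicate name '%s'", ent$name),
               "im_collision_error")
    }
    flat_names_seen <<- c(flat_names_seen, ent$name)
    flat$entries[[ent$name]] <<- ent
  }

  walk <- function(e, path, parent_subst, wired_above) {
    prefix <- paste(path, collapse = "_")
    pre <- function(nm) if (nzchar(prefix)) paste(prefix, nm, sep = "_") else nm
    wired_here <- vapply(e$inputs %||% list(), function(w) w$local, "")
    wired <- c(wired_above, wired_here)
    frame <- list()
    for (nm in env_names(e)) {
      if (is_entity(e$entries[[nm]])) frame[[nm]] <- ex_sym(pre(nm))
    }
    for (ent in env_entities(e)) {
      if (ent$kind == "REACTION") {
        for (s in ent$states) frame[[s]] <- ex_sym(pre(s))
      }
    }
    chain <- subst_env(frame, parent_subst)
    skip <- c(.reserved_globals, wired)
    check_resolved <- function(expr, extra_bound = character(0)) {
      for (fv in free_vars(expr)) {
        if (fv %in% extra_bound || fv %in% skip) next
        if (is.null(subst_lookup(chain, fv))) {
          im_error(sprintf(
            "unresolved reference '%s' in component '%s'", fv,
            if (nzchar(prefix)) prefix else "<root>"), "im_unresolved_error")
        }
      }
    }
    rewrite <- function(expr, extra_skip = character(0)) {
      check_resolved(expr, extra_skip)
      subst(expr, chain, skip = c(skip, extra_skip))
    }
    for (ent in env_entities(e)) {
      new <- ent
      new$name <- pre(ent$name)
      if (ent$kind %in% c("PARAMETER", "ASSIGNMENT")) {
        new$rhs <- rewrite(ent$rhs)
      } else if (ent$kind == "RELATION") {
        new$rhs <- rewrite(ent$rhs, extra_skip = ent$formals)
      } else if (ent$kind == "RATE") {
        new$state <- pre(ent$state)
        new$rhs <- rewrite(ent$rhs)
      } else if (ent$kind == "REACTION") {
        new$states <- vapply(ent$states, pre, "")
        if (!is.na(ent$open_state)) new$open_state <- pre(ent$open_state)
        new$transitions <- lapply(ent$transitions, function(tr) {
          tr$src <- pre(tr$src)
          tr$dst <- pre(tr$dst)
          tr$fwd <- rewrite(tr$fwd)
          if (!is.null(tr$rev)) tr$rev <- rewrite(tr$rev)
          tr
        })
      }
      add_flat(new)
      if (is_entity(e$entries[[ent$name]]) &&
          e$entries[[ent$name]]$kind == "REACTION") {
        for (s in new$states) {
          if (s %in% flat_names_seen) {
            im_error(sprintf("flattening collision: duplicate name '%s'", s),
                     "im_collision_error")
          }
          flat_names_seen <<- c(flat_names_seen, s)
        }
      }
    }
    rec <- list(ctype = e$ctype, cname = e$cname, prefix = prefix,
                path = path, outputs_local = e$outputs,
                outputs_flat = vapply(e$outputs, pre, ""),
                names_local = env_names(e) %||% character(0),
                names_flat = vapply(env_names(e) %||% character(0), pre, ""),
                meta = translate_meta(e$meta, pre),
                children = vapply(env_children(e), path_segment, ""))
    records[[length(records) + 1L]] <<- rec
    for (w in e$inputs %||% list()) {
      w$declared_in <- prefix
      wiring[[length(wiring) + 1L]] <<- w
    }
    for (child in env_children(e)) {
      walk(child, c(path, path_segment(child)), chain, wired)
    }
  }

  walk(env, character(0), NULL, character(0))
  flat$meta$components <- records
  flat$meta$inputs <- wiring
  flat
}

translate_gate_meta <- function(g, pre) {
  g$state <- pre(g$state)
  for (f in c("alpha", "beta", "inf", "tau")) {
    if (!is.null(g[[f]])) g[[f]] <- pre(g[[f]])
  }
  g
}

translate_meta <- function(meta, pre) {
  if (!is.null(meta$gate)) meta$gate <- translate_gate_meta(meta$gate, pre)
  if (!is.null(meta$gates)) {
    meta$gates <- lapply(meta$gates, translate_gate_meta, pre = pre)
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

find_component <- function(flat, ctype, cname) {
  Filter(function(r) identical(r$ctype, ctype) && identical(r$cname, cname),
         flat$meta$components)
}

#' Resolve input wiring declarations
#'
#' For each `(input (local from <type> <name> [output]))` declaration the
#' local identifier becomes a top-level algebraic assignment bound to the
#' flattened name of the source component's exported value; for example
#' `input (cai from decaying-pool ca)` with `ca` exporting `cac` yields
#' `cai = ca_cac`.
#'
#' @param flat A flattened environment from [flatten()].
#' @param decls Input declarations; defaults to the ones collected during
#'   flattening.
#' @return The environment extended with one assignment per wired name.
#' @export
resolve_inputs <- function(flat, decls = NULL) {
  decls <- decls %||% flat$meta$inputs
  bound <- list()
  for (w in decls) {
    recs <- find_component(flat, w$src_ctype, w$src_cname)
    if (length(recs) == 0L) {
      wiring_error(sprintf(
        "input '%s': no component of type '%s' named '%s'",
        w$local, w$src_ctype, w$src_cname))
    }
    if (length(recs) > 1L) {
      wiring_error(sprintf(
        "input '%s': multiple components of type '%s' named '%s'",
        w$local, w$src_ctype, w$src_cname))
    }
    rec <- recs[[1L]]
    src_flat <- if (!is.na(w$output)) {
      if (identical(w$output, "i") && identical(w$src_ctype, "Ohmic-current")) {
        # the assembled current value of a current component
        paste0("i_", sanitize_segment(w$src_cname))
      } else {
        idx <- match(w$output, rec$outputs_local)
        if (is.na(idx)) {
          wiring_error(sprintf(
            "input '%s': component '%s' does not export '%s'",
            w$local, w$src_cname, w$output))
        }
        rec$outputs_flat[[idx]]
      }
    } else {
      if (length(rec$outputs_flat) == 0L) {
        wiring_error(sprintf(
          "input '%s': component '%s' exports nothing", w$local, w$src_cname))
      }
      if (length(rec$outputs_flat) > 1L) {
        wiring_error(sprintf(
          "input '%s': component '%s' exports %d values; name one explicitly",
          w$local, w$src_cname, length(rec$outputs_flat)))
      }
      rec$outputs_flat[[1L]]
    }
    if (!is.null(bound[[w$local]])) {
      if (!identical(bound[[w$local]], src_flat)) {
        wiring_error(sprintf(
          "input '%s' is wired to two different sources ('%s' and '%s')",
          w$local, bound[[w$local]], src_flat))
      }
      next
    }
    bound[[w$local]] <- src_flat
    if (identical(w$local, src_flat)) next
    flat <- extend_env(flat, ent_assignment(w$local, ex_sym(src_flat)))
  }
  flat
}
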