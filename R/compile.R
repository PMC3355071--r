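# Pipeline driver: source text -> component tree -> nested environments ->
# flat environment -> current/membrane assembly -> ordered ODE system.

is_experiment_type <- function(ctype) ctype %in% c("simulation", "voltage-clamp")

strip_experiments <- function(comp) {
  exps <- Filter(function(c) is_experiment_type(c$ctype), comp$children)
  comp$children <- Filter(function(c) !is_experiment_type(c$ctype),
                          comp$children)
  list(comp = comp, experiments = exps)
}

child_records <- function(flat, rec) {
  Filter(function(r) length(r$path) == length(rec$path) + 1L &&
           identical(r$path[seq_along(rec$path)], rec$path),
         flat$meta$components)
}

ion_token <- function(cname) {
  tok <- tolower(cname)
  if (tok %in% c("leak", "lkg", "pas")) "non-specific" else tok
}

wired_locals <- function(flat) {
  vapply(flat$meta$inputs %||% list(), function(w) w$local, "")
}

single_output <- function(rec, what) {
  if (length(rec$outputs_flat) != 1L) {
    structural_error(sprintf("%s component '%s' must export exactly one value",
                             what, rec$prefix))
  }
  rec$outputs_flat[[1L]]
}

# Gather the normalized current description for one Ohmic-current
# component record in the flattened environment.
current_spec_from <- function(flat, rec) {
  kids <- child_records(flat, rec)
  pore <- Filter(function(r) r$ctype == "pore", kids)
  perm <- Filter(function(r) r$ctype == "permeability", kids)
  ionr <- Filter(function(r) r$ctype == "permeating-ion", kids)
  law <- if (length(perm) == 1L) "GHK" else "OHMIC"

  gbar <- if (length(pore) == 1L) {
    single_output(pore[[1L]], "pore")
  } else if (length(perm) == 1L) {
    single_output(perm[[1L]], "permeability")
  } else {
    nm <- paste0(rec$prefix, "_g_max")
    if (is.null(flat$entries[[nm]])) {
      structural_error(sprintf("current '%s' has no conductance source",
                               rec$cname))
    }
    nm
  }

  ion <- if (length(ionr) == 1L && !is.na(ionr[[1L]]$cname)) {
    ion_token(ionr[[1L]]$cname)
  } else {
    ion_token(rec$cname)
  }

  gates <- lapply(rec$meta$gates %||% list(), function(g) {
    list(state = g$state, power = g$power)
  })
  for (nm in rec$names_flat) {
    ent <- flat$entries[[nm]]
    if (is_entity(ent) && ent$kind == "REACTION") {
      if (is.na(ent$open_state)) {
        validation_error(sprintf(
          "kinetic scheme '%s' used as a gate must declare an open state",
          ent$name))
      }
      gates[[length(gates) + 1L]] <- list(state = ent$open_state,
                                          power = ent$open_power)
    }
  }

  wired <- wired_locals(flat)
  if (law == "GHK") {
    irec <- ionr[[1L]]
    valence <- irec$meta$valence
    if (is.null(valence) || is.na(valence)) {
      validation_error(sprintf(
        "GHK current '%s': permeating-ion must declare a valence", rec$cname))
    }
    conc_ref <- function(side) {
      local <- paste0(ion, side)
      idx <- match(local, irec$names_local)
      if (!is.na(idx)) return(irec$names_flat[[idx]])
      if (local %in% wired) return(local)
      NA_character_
    }
    current_spec(rec$prefix, "GHK", ion, gates, gbar,
                 conc_in = conc_ref("i"), conc_out = conc_ref("o"),
                 valence = valence)
  } else {
    e_rev <- if (length(ionr) == 1L && length(ionr[[1L]]$outputs_flat) >= 1L) {
      ionr[[1L]]$outputs_flat[[1L]]
    } else {
      nm <- paste0(rec$prefix, "_E")
      if (is.null(flat$entries[[nm]])) {
        structural_error(sprintf("current '%s' has no reversal potential",
                                 rec$cname))
      }
      nm
    }
    current_spec(rec$prefix, "OHMIC", ion, gates, gbar, e_rev = e_rev)
  }
}

#' Lower a model description to a flat environment of equations
#'
#' Runs the semantic transformation chain: component parsing, structural
#' validation, nested environment construction, flattening, current and
#' pool assembly, input wiring, and the membrane-potential equation. The
#' result is a single-namespace environment ready for [order_entities()]
#' and [build_ode_system()].
#'
#' @param x Model source text, a parsed SyntaxNode, or a ComponentDecl.
#' @return A flattened environment; `$meta` carries component, current and
#'   pool metadata.
#' @export
lower_model <- function(x) {
  comp <- as_component(x)
  validate_model_structure(comp)
  comp <- strip_experiments(comp)$comp
  nested <- build_component_env(comp)
  flat <- flatten(nested)

  current_recs <- Filter(function(r) r$ctype == "Ohmic-current",
                         flat$meta$components)
  currents <- list()
  for (rec in current_recs) {
    spec <- current_spec_from(flat, rec)
    ents <- if (spec$law == "OHMIC") {
      assemble_ohmic_current(spec)
    } else {
      assemble_ghk_current(spec)
    }
    for (e in ents) flat <- extend_env(flat, e)
    currents[[length(currents) + 1L]] <-
      list(name = rec$cname, prefix = rec$prefix, law = spec$law,
           ion = spec$ion, i_name = paste0(rec$prefix, "_i"),
           alias = paste0("i_", rec$prefix),
           g_name = if (spec$law == "OHMIC") paste0(rec$prefix, "_g")
                    else NA_character_,
           gbar = spec$gbar, e_rev = spec$e_rev,
           conc_in = spec$conc_in, conc_out = spec$conc_out,
           valence = spec$valence,
           gates = rec$meta$gates %||% list(),
           reactions = Filter(function(nm) {
             e <- flat$entries[[nm]]
             is_entity(e) && e$kind == "REACTION"
           }, rec$names_flat),
           range = rec$names_flat)
  }
  flat$meta$currents <- currents

  pool_recs <- Filter(function(r) r$ctype == "decaying-pool",
                      flat$meta$components)
  flat$meta$pools <- lapply(pool_recs, function(r) {
    p <- r$meta$pool
    pre <- prefix_names(r$path)
    list(name = p$name, ion = ion_token(p$name), prefix = r$prefix,
         sources = p$sources, exported = pre(p$exported),
         steady = pre("steady"), tau = pre("tau"), b = pre("b"))
  })

  flat <- resolve_inputs(flat)
  if (is.null(flat$entries[["celsius"]])) {
    flat <- extend_env(flat, ent_parameter("celsius", ex_num(22)))
  }
  flat <- extend_env(flat, assemble_membrane_potential(flat))
  flat$meta$model_name <- if (is.na(comp$cname)) "model" else comp$cname
  flat
}

as_component <- function(x) {
  if (inherits(x, "im_component")) return(x)
  ast <- if (is.character(x)) parse_sexpr(x) else x
  parse_component(ast)
}

#' Compile a model description end to end
#'
#' Convenience wrapper running [lower_model()], [order_entities()],
#' [build_ode_system()] and [build_model_info()], and building the
#' simulation / voltage-clamp experiment descriptions declared alongside
#' the model.
#'
#' @param x Model source text (s-expression), a SyntaxNode (e.g. from
#'   [parse_xml()]), or a ComponentDecl.
#' @return An object of class `im_model` with fields `env` (flat
#'   environment), `sys` (ODE system), `info` (per-current metadata),
#'   `sim` (simulation configuration or NULL) and `clamps` (list of
#'   voltage-clamp protocols).
#' @examples
#' m <- compile_model(hh_fixture())
#' names(m$sys$state_index)
#' @export
compile_model <- function(x) {
  comp <- as_component(x)
  parts <- strip_experiments(comp)
  env <- lower_model(comp)
  ordered <- order_entities(env)
  sys <- build_ode_system(ordered)
  info <- build_model_info(sys)
  sims <- Filter(function(c) c$ctype == "simulation", parts$experiments)
  clamps <- Filter(function(c) c$ctype == "voltage-clamp", parts$experiments)
  structure(list(
    name = env$meta$model_name,
    components = comp,
    env = env,
    ordered = ordered,
    sys = sys,
    info = info,
    sim = if (length(sims) >= 1L) build_sim_config(sims[[1L]]) else NULL,
    clamps = lapply(clamps, build_clamp_protocol, model = env)
  ), class = "im_model")
}

#' @export
print.im_model <- function(x, ...) {
  cat(sprintf("<model '%s': %d state(s), %d current(s)>\n", x$name,
              length(x$sys$state_index), length(x$env$meta$currents)))
  invisible(x)
}
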