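# Dependency ordering of the flattened environment and construction of the
# solver-ready system representation: an ordered list of parameters and
# algebraic assignments, a list of relations, the list of differential
# equations, and a dense integer index for the state variables.

cycle_error <- function(names) {
  im_error(sprintf("circular dependency among assignments: %s",
                   paste(names, collapse = " -> ")), "im_cycle_error")
}

system_states <- function(env) {
  states <- character(0)
  for (ent in env_entities(env)) {
    if (ent$kind == "RATE") states <- c(states, ent$state)
    if (ent$kind == "REACTION") states <- c(states, ent$states)
  }
  states
}

#' Order a flattened environment by expression dependencies
#'
#' Parameters and algebraic assignments are topologically sorted so that
#' each entry appears after every entry it references; states, the
#' reserved globals and relation formals are roots. Ties are broken by
#' stable source order, so emission is deterministic. Circular assignments
#' and mutually recursive relations are errors.
#'
#' @param flat A flattened environment (see [flatten()], [lower_model()]).
#' @return The environment with entries reordered: ordered
#'   parameters/assignments, then relations, then rate equations, then
#'   kinetic schemes.
#' @export
order_entities <- function(flat) {
  ents <- env_entities(flat)
  defs <- Filter(function(e) e$kind %in% c("PARAMETER", "ASSIGNMENT"), ents)
  rels <- Filter(function(e) e$kind == "RELATION", ents)
  rates <- Filter(function(e) e$kind == "RATE", ents)
  reactions <- Filter(function(e) e$kind == "REACTION", ents)
  def_names <- vapply(defs, function(e) e$name, "")

  deps <- lapply(defs, function(e) intersect(free_vars(e$rhs), def_names))
  names(deps) <- def_names
  # Assignments may also depend on defs *through* a relation body (relations
  # are emitted as functions, so only ordering among defs matters here).
  placed <- character(0)
  remaining <- seq_along(defs)
  ordered <- list()
  while (length(remaining) > 0L) {
    progress <- FALSE
    for (i in remaining) {
      if (all(deps[[def_names[[i]]]] %in% placed)) {
        ordered[[length(ordered) + 1L]] <- defs[[i]]
        placed <- c(placed, def_names[[i]])
        remaining <- setdiff(remaining, i)
        progress <- TRUE
        break
      }
    }
    if (!progress) {
      # every remaining def waits on another remaining def: extract a cycle
      left <- def_names[remaining]
      start <- left[[1L]]
      path <- start
      cur <- start
      repeat {
        nxt <- intersect(deps[[cur]], left)[[1L]]
        if (nxt %in% path) {
          cyc <- c(path[seq(match(nxt, path), length(path))], nxt)
          cycle_error(cyc)
        }
        path <- c(path, nxt)
        cur <- nxt
      }
    }
  }

  # Relations must not be mutually recursive.
  rel_names <- vapply(rels, function(e) e$name, "")
  rel_deps <- lapply(rels, function(e) {
    intersect(applied_relations(e$rhs), rel_names)
  })
  names(rel_deps) <- rel_names
  visit_state <- stats::setNames(rep(0L, length(rel_names)), rel_names)
  visit <- function(nm, stack) {
    if (visit_state[[nm]] == 2L) return(invisible(NULL))
    if (visit_state[[nm]] == 1L) {
      cycle_error(c(stack[seq(match(nm, stack), length(stack))], nm))
    }
    visit_state[[nm]] <<- 1L
    for (d in rel_deps[[nm]]) visit(d, c(stack, nm))
    visit_state[[nm]] <<- 2L
  }
  for (nm in rel_names) visit(nm, character(0))

  out <- flat
  out$entries <- list()
  for (e in c(ordered, rels, rates, reactions)) out$entries[[e$name]] <- e
  out
}

#' Build the solver-ready system representation
#'
#' Constructs the 5-tuple representation: topologically ordered parameters
#' and algebraic assignments, the list of relations, the list of
#' differential equations (kinetic schemes expanded to one equation per
#' state via [expand_reaction()]), and a dense 0-based index over the
#' state variables (`v` first when present, then in insertion order).
#'
#' @param ordered An environment from [order_entities()].
#' @return An object of class `im_ode_system` with fields `ordered_defs`,
#'   `relations`, `odes` (list of `list(state, rhs)`), `state_index`
#'   (named 0-based integers) and `reactions` (the unexpanded schemes, for
#'   initialization and conservation checks).
#' @export
build_ode_system <- function(ordered) {
  ents <- env_entities(ordered)
  defs <- Filter(function(e) e$kind %in% c("PARAMETER", "ASSIGNMENT"), ents)
  rels <- Filter(function(e) e$kind == "RELATION", ents)
  rates <- Filter(function(e) e$kind == "RATE", ents)
  reactions <- Filter(function(e) e$kind == "REACTION", ents)

  odes <- list()
  for (r in rates) odes[[r$state]] <- r$rhs
  for (rx in reactions) {
    for (r in expand_reaction(rx)) odes[[r$state]] <- r$rhs
  }
  if (length(odes) == 0L) {
    im_error("model defines no differential equations (empty system)",
             "im_empty_system_error")
  }
  states <- names(odes)
  if ("v" %in% states) states <- c("v", setdiff(states, "v"))
  state_index <- stats::setNames(seq_along(states) - 1L, states)

  structure(list(
    ordered_defs = defs,
    relations = stats::setNames(rels, vapply(rels, function(e) e$name, "")),
    odes = lapply(states, function(s) list(state = s, rhs = odes[[s]])),
    state_index = state_index,
    reactions = reactions,
    meta = ordered$meta
  ), class = "im_ode_system")
}

#' @export
print.im_ode_system <- function(x, ...) {
  cat(sprintf("<ode system: %d states, %d defs, %d relations, %d kinetic scheme(s)>\n",
              length(x$state_index), length(x$ordered_defs),
              length(x$relations), length(x$reactions)))
  cat("states:", paste(names(x$state_index), collapse = ", "), "\n")
  invisible(x)
}

#' Extract per-current metadata for NMODL generation
#'
#' One record per ionic current: the current variable, the permeating ion
#' species, the accumulating ion (when a decaying pool consumes the
#' current), the reversal-potential name for specific ions, and the range
#' variables owned by the mechanism. Names are built by string
#' concatenation from the species token (`i` + ion, `e` + ion), following
#' the NEURON convention.
#'
#' @param x An `im_ode_system` (or a lowered environment with current
#'   metadata).
#' @return An object of class `im_model_info` (list of records).
#' @export
build_model_info <- function(x) {
  meta <- if (inherits(x, "im_ode_system")) x$meta else x$meta
  currents <- meta$currents
  if (is.null(currents) || length(currents) == 0L) {
    structural_error("no currents: run the current assembly first")
  }
  pools <- meta$pools %||% list()
  recs <- lapply(currents, function(cu) {
    acc <- NA_character_
    for (p in pools) {
      if (cu$name %in% p$sources) acc <- p$ion
    }
    list(current = cu$name,
         i_var = cu$alias,
         ion = cu$ion,
         ion_current = if (identical(cu$ion, "non-specific")) NA_character_
                       else paste0("i", cu$ion),
         reversal = if (cu$law == "OHMIC" && !identical(cu$ion, "non-specific"))
                      paste0("e", cu$ion) else NA_character_,
         acc_ion = acc,
         law = cu$law,
         range = cu$range)
  })
  names_seen <- vapply(recs, function(r) r$current, "")
  if (anyDuplicated(names_seen)) {
    im_error(sprintf("two currents generate the same name '%s'",
                     names_seen[duplicated(names_seen)][[1L]]),
             "im_collision_error")
  }
  structure(recs, class = "im_model_info")
}
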