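# Entities and environments: the intermediate semantic form between the
# declarative syntax and the flat ODE system.
#
# An entity is a named semantic object of exactly one kind:
#   PARAMETER   constant during integration
#   ASSIGNMENT  algebraic equation
#   RELATION    function of formal arguments
#   RATE        first-order ODE d(state)/dt = rhs
#   REACTION    Markov kinetic scheme (mass-action transitions)

ent_parameter <- function(name, rhs, unit = NA_character_) {
  structure(list(name = name, kind = "PARAMETER", rhs = rhs, unit = unit),
            class = "im_entity")
}

ent_assignment <- function(name, rhs) {
  structure(list(name = name, kind = "ASSIGNMENT", rhs = rhs),
            class = "im_entity")
}

ent_relation <- function(name, formals, rhs) {
  structure(list(name = name, kind = "RELATION",
                 formals = as.character(formals), rhs = rhs),
            class = "im_entity")
}

ent_rate <- function(name, rhs, initial = NA_real_) {
  structure(list(name = name, kind = "RATE", state = name, rhs = rhs,
                 initial = initial),
            class = "im_entity")
}

# transitions: list of list(src, dst, fwd = Expr, rev = Expr or NULL)
ent_reaction <- function(name, states, transitions, conserve = 1,
                         open_state, open_power = 1L) {
  states <- as.character(states)
  for (tr in transitions) {
    if (!tr$src %in% states || !tr$dst %in% states) {
      im_error(sprintf(
        "reaction '%s': transition %s -> %s references an undeclared state",
        name, tr$src, tr$dst), "im_grammar_error")
    }
  }
  # Connectivity of the (undirected) transition graph.
  if (length(states) > 1L) {
    seen <- states[[1L]]
    repeat {
      grew <- FALSE
      for (tr in transitions) {
        if (tr$src %in% seen && !tr$dst %in% seen) {
          seen <- c(seen, tr$dst); grew <- TRUE
        }
        if (tr$dst %in% seen && !tr$src %in% seen) {
          seen <- c(seen, tr$src); grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (length(seen) < length(states)) {
      im_error(sprintf("reaction '%s': transition graph is disconnected (%s unreachable)",
                       name, paste(setdiff(states, seen), collapse = ", ")),
               "im_grammar_error")
    }
  }
  if (!is.null(open_state) && !is.na(open_state) && !open_state %in% states) {
    im_error(sprintf("reaction '%s': open state '%s' is not a declared state",
                     name, open_state), "im_grammar_error")
  }
  structure(list(name = name, kind = "REACTION", states = states,
                 transitions = transitions, conserve = as.double(conserve),
                 open_state = open_state, open_power = as.integer(open_power)),
            class = "im_entity")
}

is_entity <- function(x) inherits(x, "im_entity")

## -------------------------------------------------------- declarations ----

#' Build an entity from one declaration
#'
#' Maps the six declaration forms of the equation layer to typed entities:
#' `(const x = e)` to PARAMETER, `(x = e)` to ASSIGNMENT,
#' `(fun f (a ...) = e)` to RELATION, `(d (x) = e)` to RATE, and
#' `(reaction name (transitions (<- S1 S2 (fwd) (rev)) ...) (conserve c)
#' (open O (power p)))` to REACTION (both forward-only `(<- S1 S2 (fwd))`
#' and reversible transitions are accepted; `conserve` defaults to 1,
#' `power` to 1).
#'
#' @param decl A SyntaxNode for one declaration.
#' @return An entity object.
#' @examples
#' build_entity(parse_sexpr("(const duration = 2000)"))
#' @export
build_entity <- function(decl) {
  if (!is_node(decl)) grammar_error("declaration must be a parenthesized form")
  head <- node_head(decl)
  ch <- decl$children
  expect_eq_at <- function(i, what) {
    if (length(ch) < i || !is_op_atom(ch[[i]], "=")) {
      grammar_error(sprintf("expected '=' in %s declaration", what))
    }
  }
  if (identical(head, "const")) {
    if (length(ch) < 4L || !is_sym(ch[[2L]])) {
      grammar_error("const declaration must be (const name = value)")
    }
    expect_eq_at(3L, "const")
    rest <- ch[-(1:3)]
    rhs <- parse_expr_items(rest)
    if (length(free_vars(rhs)) > 0L) {
      grammar_error(sprintf(
        "const '%s': right-hand side must be a literal (free: %s)",
        ch[[2L]]$name, paste(free_vars(rhs), collapse = ", ")))
    }
    unit <- NA_character_
    if (length(rest) == 1L && is_num_atom(rest[[1L]])) unit <- rest[[1L]]$unit
    return(ent_parameter(ch[[2L]]$name, rhs, unit))
  }
  if (identical(head, "fun")) {
    if (length(ch) < 5L || !is_sym(ch[[2L]]) || !is_node(ch[[3L]])) {
      grammar_error("relation must be (fun name (formals) = expr)")
    }
    expect_eq_at(4L, "fun")
    formals <- vapply(ch[[3L]]$children, function(a) {
      if (!is_sym(a)) grammar_error("relation formals must be identifiers")
      a$name
    }, "")
    return(ent_relation(ch[[2L]]$name, formals,
                        parse_expr_items(ch[-(1:4)])))
  }
  if (identical(head, "d")) {
    if (length(ch) < 4L || !is_node(ch[[2L]]) ||
        length(ch[[2L]]$children) != 1L || !is_sym(ch[[2L]]$children[[1L]])) {
      grammar_error("rate equation must be (d (state) = expr)")
    }
    expect_eq_at(3L, "rate")
    return(ent_rate(ch[[2L]]$children[[1L]]$name,
                    parse_expr_items(ch[-(1:3)])))
  }
  if (identical(head, "reaction")) {
    return(build_reaction(decl))
  }
  # Algebraic assignment: (name = expr)
  if (length(ch) >= 3L && is_sym(ch[[1L]]) && is_op_atom(ch[[2L]], "=")) {
    return(ent_assignment(ch[[1L]]$name, parse_expr_items(ch[-(1:2)])))
  }
  if (is.na(head)) grammar_error("unknown declaration form")
  grammar_error(sprintf("unknown declaration head '%s'", head))
}

build_reaction <- function(decl) {
  ch <- decl$children
  if (length(ch) < 3L) grammar_error("reaction needs a name and clauses")
  name_item <- ch[[2L]]
  rname <- if (is_sym(name_item)) {
    name_item$name
  } else if (is_node(name_item) && length(name_item$children) == 1L &&
             is_sym(name_item$children[[1L]])) {
    name_item$children[[1L]]$name
  } else {
    grammar_error("reaction name must be an identifier")
  }
  transitions <- NULL
  conserve <- 1
  open_state <- NA_character_
  open_power <- 1L
  for (cl in ch[-(1:2)]) {
    h <- node_head(cl)
    if (identical(h, "transitions")) {
      transitions <- lapply(node_args(cl), parse_transition)
    } else if (identical(h, "conserve")) {
      cexpr <- parse_expr_items(node_args(cl))
      if (length(free_vars(cexpr)) > 0L) {
        grammar_error("conserve total must be a literal")
      }
      conserve <- eval_expr(cexpr)
    } else if (identical(h, "open")) {
      args <- node_args(cl)
      if (length(args) < 1L || !is_sym(args[[1L]])) {
        grammar_error("open clause must name a state")
      }
      open_state <- args[[1L]]$name
      if (length(args) >= 2L && is_node(args[[2L]]) &&
          identical(node_head(args[[2L]]), "power")) {
        open_power <- as.integer(args[[2L]]$children[[2L]]$value)
      }
    } else {
      grammar_error(sprintf("unknown reaction clause '%s'", h))
    }
  }
  if (is.null(transitions) || length(transitions) == 0L) {
    grammar_error(sprintf("reaction '%s' has no transitions", rname))
  }
  states <- unique(unlist(lapply(transitions, function(tr) c(tr$src, tr$dst))))
  ent_reaction(rname, states, transitions, conserve, open_state, open_power)
}

parse_transition <- function(tr) {
  if (!is_node(tr)) grammar_error("transition must be (<- src dst (fwd) (rev))")
  ch <- tr$children
  if (length(ch) < 4L || !is_sym(ch[[1L]]) ||
      !ch[[1L]]$name %in% c("<-", "<->") ||
      !is_sym(ch[[2L]]) || !is_sym(ch[[3L]])) {
    grammar_error("transition must be (<- src dst (fwd) [(rev)])")
  }
  fwd <- parse_expr_node(ch[[4L]])
  rev <- if (length(ch) >= 5L) parse_expr_node(ch[[5L]]) else NULL
  list(src = ch[[2L]]$name, dst = ch[[3L]]$name, fwd = fwd, rev = rev)
}

## --------------------------------------------------------- environments ----

#' Create an empty entity environment
#'
#' An environment maps names to entities or child environments and carries
#' component metadata (type, name, declared outputs). Environments are
#' persistent: [extend_env()] returns a new environment and never mutates
#' its argument.
#'
#' @param ctype,cname Component type and name, or `NA`.
#' @param outputs Character vector of exported names.
#' @export
env_new <- function(ctype = NA_character_, cname = NA_character_,
                    outputs = character(0)) {
  structure(list(entries = list(), ctype = ctype, cname = cname,
                 outputs = outputs, meta = list()),
            class = "im_env")
}

is_env <- function(x) inherits(x, "im_env")

entry_name <- function(x) {
  if (is_entity(x)) return(x$name)
  if (is_env(x)) {
    nm <- if (!is.na(x$cname)) x$cname else x$ctype
    if (is.na(nm)) im_error("child environment has neither name nor type",
                            "im_grammar_error")
    return(nm)
  }
  im_error("environment entries must be entities or environments",
           "im_grammar_error")
}

#' Extend an environment with an entity or child environment
#'
#' @param env An environment from [env_new()].
#' @param x An entity ([build_entity()]) or a child environment.
#' @param name Binding name; defaults to the entity name or the child
#'   component's name/type.
#' @return A new environment; the original is unchanged.
#' @export
extend_env <- function(env, x, name = NULL) {
  if (is.null(name)) name <- entry_name(x)
  if (!is.null(env$entries[[name]])) {
    im_error(sprintf("redefinition of '%s'", name), "im_redef_error")
  }
  env$entries[[name]] <- x
  env
}

env_get <- function(env, name) env$entries[[name]]

env_names <- function(env) names(env$entries)

# Entities of a given kind, in insertion order.
env_entities <- function(env, kind = NULL) {
  es <- Filter(is_entity, env$entries)
  if (!is.null(kind)) es <- Filter(function(e) e$kind %in% kind, es)
  es
}

env_children <- function(env) Filter(is_env, env$entries)
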