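# Arithmetic expression ASTs -- the right-hand sides of all equations.
#
# Variants:
#   ex_num(value)        numeric literal
#   ex_sym(name)         identifier
#   ex_neg(arg)          unary minus
#   ex_bin(op, l, r)     binary + - * / ^
#   ex_app(fun, args)    application of a relation or built-in function

ex_num <- function(value) list(k = "num", v = as.double(value))
ex_sym <- function(name) list(k = "sym", name = name)
ex_neg <- function(arg) list(k = "neg", arg = arg)
ex_bin <- function(op, l, r) list(k = "bin", op = op, l = l, r = r)
ex_app <- function(fun, args) list(k = "app", fun = fun, args = args)

is_expr <- function(x) is.list(x) && !is.null(x$k) &&
  x$k %in% c("num", "sym", "neg", "bin", "app")

# Built-in functions available in every target language. `ghk` is the
# constant-field flux (see ghk_flux); it is emitted as a helper in generated
# code.
.builtin_funs <- c("exp", "log", "log10", "sqrt", "sin", "cos", "tan",
                   "tanh", "abs", "ghk")

.prec <- c("+" = 1L, "-" = 1L, "*" = 2L, "/" = 2L, "^" = 4L)

## ------------------------------------------------- infix token parsing ----

# Parse a sequence of SyntaxNode children (atoms and parenthesized groups)
# as an infix arithmetic expression. A parenthesized group whose first
# child is a symbol and that contains no top-level operator tokens is read
# as prefix application `(exp x)`; a symbol immediately followed by a group
# is read as application `exp(x)`; everything else is grouping.
parse_expr_items <- function(items) {
  pos <- 1L
  n <- length(items)
  peek <- function() if (pos <= n) items[[pos]] else NULL
  advance <- function() {
    x <- items[[pos]]
    pos <<- pos + 1L
    x
  }
  parse_primary <- function() {
    x <- peek()
    if (is.null(x)) grammar_error("unexpected end of expression")
    if (is_num_atom(x)) {
      advance()
      return(ex_num(x$value))
    }
    if (is_sym(x)) {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && is_node(nxt)) {
        advance()
        return(ex_app(x$name, split_args(nxt$children)))
      }
      return(ex_sym(x$name))
    }
    if (is_node(x)) {
      advance()
      return(parse_group(x))
    }
    if (is_op_atom(x)) {
      grammar_error(sprintf("unexpected operator '%s' in expression", x$op))
    }
    grammar_error("unexpected token in expression")
  }
  parse_unary <- function() {
    x <- peek()
    if (is_op_atom(x, "-")) {
      advance()
      return(ex_neg(parse_unary()))
    }
    if (is_op_atom(x, "+")) {
      advance()
      return(parse_unary())
    }
    parse_primary()
  }
  parse_binary <- function(min_prec) {
    lhs <- parse_unary()
    repeat {
      x <- peek()
      if (is.null(x) || !is_op_atom(x) || is.null(.prec[x$op]) ||
          is.na(.prec[x$op]) || .prec[x$op] < min_prec) {
        return(lhs)
      }
      op <- x$op
      advance()
      next_min <- if (op == "^") .prec[op] else .prec[op] + 1L
      rhs <- parse_binary(next_min)
      lhs <- ex_bin(op, lhs, rhs)
    }
  }
  e <- parse_binary(1L)
  if (pos <= n) {
    x <- items[[pos]]
    what <- if (is_op_atom(x)) x$op else if (is_sym(x)) x$name else "token"
    grammar_error(sprintf("trailing '%s' in expression", what))
  }
  e
}

# Group: application form vs parenthesized infix.
parse_group <- function(node) {
  ch <- node$children
  if (length(ch) == 0L) grammar_error("empty () in expression")
  has_top_op <- any(vapply(ch, function(x) is_op_atom(x), TRUE))
  if (length(ch) >= 2L && is_sym(ch[[1L]]) && !has_top_op) {
    args <- lapply(ch[-1L], function(a) {
      if (is_node(a)) parse_expr_items(a$children) else parse_expr_items(list(a))
    })
    return(ex_app(ch[[1L]]$name, args))
  }
  parse_expr_items(ch)
}

# Split children of an argument list on top-level commas.
split_args <- function(children) {
  args <- list()
  cur <- list()
  for (x in children) {
    if (is_op_atom(x, ",")) {
      args[[length(args) + 1L]] <- cur
      cur <- list()
    } else {
      cur[[length(cur) + 1L]] <- x
    }
  }
  args[[length(args) + 1L]] <- cur
  lapply(args, parse_expr_items)
}

# Entry point used by the equation layer: parse the expression spanning a
# declaration tail (a list of SyntaxNodes) or a single node.
parse_expr_node <- function(x) {
  if (is_expr(x)) return(x)
  if (is.list(x) && is.null(x$kind) && is.null(x$k)) {
    return(parse_expr_items(x))
  }
  parse_expr_items(list(x))
}

## ----------------------------------------------------------- free vars ----

#' Free variables of an expression
#'
#' Returns the identifiers occurring in variable position. Names in applied
#' (function) position are not included: they are tracked separately as
#' relation dependencies (see the code generator), matching how relations
#' are kept as callable definitions rather than values.
#'
#' @param e An expression AST (internal `ex_*` form).
#' @return Character vector of identifier names (no duplicates, in first
#'   occurrence order).
#' @export
free_vars <- function(e) {
  acc <- character(0)
  walk <- function(x) {
    switch(x$k,
      num = NULL,
      sym = acc[[length(acc) + 1L]] <<- x$name,
      neg = walk(x$arg),
      bin = { walk(x$l); walk(x$r) },
      app = for (a in x$args) walk(a)
    )
    invisible(NULL)
  }
  walk(e)
  unique(acc)
}

# Names of user relations applied anywhere in an expression.
applied_relations <- function(e) {
  acc <- character(0)
  walk <- function(x) {
    switch(x$k,
      neg = walk(x$arg),
      bin = { walk(x$l); walk(x$r) },
      app = {
        if (!x$fun %in% .builtin_funs) acc[[length(acc) + 1L]] <<- x$fun
        for (a in x$args) walk(a)
      }
    )
    invisible(NULL)
  }
  walk(e)
  unique(acc)
}

## --------------------------------------------------------- substitution ----

#' Build a substitution environment
#'
#' A substitution environment maps identifiers to replacement expressions.
#' Environments chain: when an identifier is not found in the immediate
#' frame it is looked up in the enclosing frame, and so on. Identifiers
#' absent from every frame pass through unchanged.
#'
#' @param frame Named list of expression ASTs (or character strings, which
#'   are taken as replacement identifiers).
#' @param parent An enclosing substitution environment, or `NULL`.
#' @export
subst_env <- function(frame = list(), parent = NULL) {
  frame <- lapply(frame, function(v) if (is.character(v)) ex_sym(v) else v)
  structure(list(frame = frame, parent = parent), class = "im_subst_env")
}

subst_lookup <- function(s, name) {
  while (!is.null(s)) {
    if (!is.null(s$frame[[name]])) return(s$frame[[name]])
    s <- s$parent
  }
  NULL
}

#' Substitute identifiers in an expression
#'
#' Every free occurrence of an identifier mapped by the substitution
#' environment is replaced by its image; applied relation names are renamed
#' when the image is itself an identifier. Unmapped identifiers are left
#' unchanged.
#'
#' @param e Expression AST.
#' @param s A substitution environment from [subst_env()], or a named list
#'   (coerced with [subst_env()]).
#' @param skip Identifiers to leave untouched (e.g. relation formals).
#' @export
subst <- function(e, s, skip = character(0)) {
  if (!inherits(s, "im_subst_env")) s <- subst_env(s)
  walk <- function(x) {
    switch(x$k,
      num = x,
      sym = {
        if (x$name %in% skip) return(x)
        r <- subst_lookup(s, x$name)
        if (is.null(r)) x else r
      },
      neg = ex_neg(walk(x$arg)),
      bin = ex_bin(x$op, walk(x$l), walk(x$r)),
      app = {
        fn <- x$fun
        if (!fn %in% .builtin_funs && !fn %in% skip) {
          r <- subst_lookup(s, fn)
          if (!is.null(r) && r$k == "sym") fn <- r$name
        }
        ex_app(fn, lapply(x$args, walk))
      }
    )
  }
  walk(e)
}

## ----------------------------------------------------------- evaluation ----

eval_error <- function(msg) {
  stop(errorCondition(msg, class = c("im_eval_error", "im_error")))
}

#' Evaluate an expression numerically
#'
#' IEEE-double evaluation. Division by zero and overflow propagate as
#' infinities/NaN, matching the behaviour of the generated code in every
#' target language.
#'
#' @param e Expression AST.
#' @param bindings Named numeric vector or list binding every free symbol.
#' @param relations Named list of RELATION entities (see [build_entity()])
#'   resolving applied relation names, or an environment built by the code
#'   generator.
#' @return A double.
#' @export
eval_expr <- function(e, bindings = list(), relations = list()) {
  b <- as.list(bindings)
  ev <- function(x, env) {
    switch(x$k,
      num = x$v,
      sym = {
        v <- env[[x$name]]
        if (is.null(v)) eval_error(sprintf("unbound symbol '%s'", x$name))
        v
      },
      neg = -ev(x$arg, env),
      bin = {
        l <- ev(x$l, env)
        r <- ev(x$r, env)
        switch(x$op,
          "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r, "^" = l ^ r)
      },
      app = {
        args <- vapply(x$args, ev, 0.0, env = env)
        if (x$fun %in% .builtin_funs) {
          return(switch(x$fun,
            exp = exp(args[[1L]]), log = log(args[[1L]]),
            log10 = log10(args[[1L]]), sqrt = sqrt(args[[1L]]),
            sin = sin(args[[1L]]), cos = cos(args[[1L]]),
            tan = tan(args[[1L]]), tanh = tanh(args[[1L]]),
            abs = abs(args[[1L]]),
            ghk = ghk_flux(args[[1L]], args[[2L]], args[[3L]], args[[4L]],
                           args[[5L]])))
        }
        rel <- relations[[x$fun]]
        if (is.null(rel)) eval_error(sprintf("undefined relation '%s'", x$fun))
        if (length(rel$formals) != length(args)) {
          eval_error(sprintf("relation '%s' expects %d argument(s), got %d",
                             x$fun, length(rel$formals), length(args)))
        }
        inner <- env
        for (i in seq_along(args)) inner[[rel$formals[[i]]]] <- args[[i]]
        ev(rel$rhs, inner)
      }
    )
  }
  ev(e, b)
}

## ------------------------------------------------------------- emission ----

# Render an expression as text for a target dialect, with minimal
# parenthesization. Deterministic.
expr_text <- function(e, dialect = c("r", "octave", "nmodl", "plain")) {
  dialect <- match.arg(dialect)
  fname <- function(f) {
    if (dialect == "nmodl" && f == "abs") return("fabs")
    f
  }
  render <- function(x, parent_prec, side) {
    switch(x$k,
      num = fmt_number(x$v),
      sym = x$name,
      neg = {
        s <- paste0("-", render(x$arg, 3L, "u"))
        if (parent_prec > 1L) paste0("(", s, ")") else s
      },
      bin = {
        p <- .prec[[x$op]]
        ls <- render(x$l, p, "l")
        rs <- render(x$r, if (x$op %in% c("-", "/")) p + 1L else p, "r")
        s <- paste0(ls, " ", x$op, " ", rs)
        if (p < parent_prec) paste0("(", s, ")") else s
      },
      app = {
        args <- vapply(x$args, render, "", parent_prec = 0L, side = "a")
        paste0(fname(x$fun), "(", paste(args, collapse = ", "), ")")
      }
    )
  }
  render(e, 0L, "t")
}

# Convert an expression to an R language object for fast evaluation.
expr_to_lang <- function(e) {
  switch(e$k,
    num = e$v,
    sym = as.name(e$name),
    neg = call("-", expr_to_lang(e$arg)),
    bin = call(e$op, expr_to_lang(e$l), expr_to_lang(e$r)),
    app = as.call(c(list(as.name(e$fun)), lapply(e$args, expr_to_lang)))
  )
}

# Render an expression back to SyntaxNode children (used when serializing
# entities).
expr_to_items <- function(e) {
  as_item <- function(x, parent_prec) {
    switch(x$k,
      num = list(im_num(x$v)),
      sym = list(im_sym(x$name)),
      neg = {
        items <- c(list(im_op("-")), as_item(x$arg, 3L))
        if (parent_prec > 1L) list(im_node(items)) else items
      },
      bin = {
        p <- .prec[[x$op]]
        items <- c(as_item(x$l, p), list(im_op(x$op)),
                   as_item(x$r, if (x$op %in% c("-", "/")) p + 1L else p))
        if (p < parent_prec) list(im_node(items)) else items
      },
      app = {
        inner <- list()
        for (i in seq_along(x$args)) {
          if (i > 1L) inner[[length(inner) + 1L]] <- im_op(",")
          for (it in as_item(x$args[[i]], 0L)) {
            inner[[length(inner) + 1L]] <- it
          }
        }
        list(im_sym(x$fun), im_node(inner))
      }
    )
  }
  as_item(e, 0L)
}
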