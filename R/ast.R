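# Syntax trees for the model-description language.
#
# A SyntaxNode is a plain list tagged by `kind`:
#   node : list(kind = "node", children = list(...))
#   sym  : list(kind = "sym",  name = <chr>)
#   num  : list(kind = "num",  value = <dbl>, unit = <chr, NA if none>)
#   op   : list(kind = "op",   op = <chr>)
# Unit annotations (e.g. `1.0 uF/cm*cm`) are lexed as one opaque token
# attached to the preceding number and are echoed on output, never
# interpreted.

im_node <- function(children) list(kind = "node", children = children)
im_sym <- function(name) list(kind = "sym", name = name)
im_num <- function(value, unit = NA_character_) {
  list(kind = "num", value = as.double(value), unit = as.character(unit))
}
im_op <- function(op) list(kind = "op", op = op)

is_node <- function(x) is.list(x) && identical(x$kind, "node")
is_sym <- function(x, name = NULL) {
  is.list(x) && identical(x$kind, "sym") &&
    (is.null(name) || identical(x$name, name))
}
is_num_atom <- function(x) is.list(x) && identical(x$kind, "num")
is_op_atom <- function(x, op = NULL) {
  is.list(x) && identical(x$kind, "op") &&
    (is.null(op) || identical(x$op, op))
}

# Head symbol of a node, or NA if the first child is not a symbol.
node_head <- function(x) {
  if (is_node(x) && length(x$children) >= 1L && is_sym(x$children[[1L]])) {
    x$children[[1L]]$name
  } else {
    NA_character_
  }
}

node_args <- function(x) x$children[-1L]

syntax_error <- function(msg, line = NA, col = NA) {
  loc <- if (!is.na(line)) sprintf(" (line %d, column %d)", line, col) else ""
  stop(errorCondition(paste0(msg, loc),
                      class = c("im_syntax_error", "im_error")))
}

grammar_error <- function(msg) {
  stop(errorCondition(msg, class = c("im_grammar_error", "im_error")))
}

im_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "im_error")))
}

## ---------------------------------------------------------------- lexer ----

.tok_pattern <- paste(
  ";[^\n]*",                                   # comment to end of line
  "\\(|\\)",
  "<->|<-",                                    # kinetic transition arrows
  "(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?",  # number
  "[A-Za-z_][A-Za-z0-9_']*(?:-[A-Za-z0-9_']+)*",         # identifier
  "[-+*/^=,]",                                 # operators
  sep = "|"
)

tokenize <- function(text) {
  m <- gregexpr(.tok_pattern, text, perl = TRUE)[[1L]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (length(starts) == 1L && starts[1L] == -1L) {
    starts <- integer(0)
    lens <- integer(0)
  }
  # Verify full coverage: anything between matches must be whitespace.
  nl_pos <- c(0L, which(strsplit(text, "", fixed = TRUE)[[1L]] == "\n"))
  line_of <- function(pos) findInterval(pos, nl_pos)
  col_of <- function(pos) pos - nl_pos[findInterval(pos, nl_pos)]
  prev_end <- 0L
  gaps <- character(0)
  for (i in seq_along(starts)) {
    if (starts[i] > prev_end + 1L) {
      gap <- substr(text, prev_end + 1L, starts[i] - 1L)
      if (grepl("[^[:space:]]", gap)) {
        bad <- prev_end + regexpr("[^[:space:]]", gap)
        syntax_error(sprintf("unexpected character '%s'",
                             substr(text, bad, bad)),
                     line_of(bad), col_of(bad))
      }
    }
    prev_end <- starts[i] + lens[i] - 1L
  }
  if (prev_end < nchar(text)) {
    tail <- substr(text, prev_end + 1L, nchar(text))
    if (grepl("[^[:space:]]", tail)) {
      bad <- prev_end + regexpr("[^[:space:]]", tail)
      syntax_error(sprintf("unexpected character '%s'",
                           substr(text, bad, bad)),
                   line_of(bad), col_of(bad))
    }
  }
  toks <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    txt <- substr(text, s, s + lens[i] - 1L)
    kind <- if (startsWith(txt, ";")) {
      "comment"
    } else if (txt == "(") {
      "lparen"
    } else if (txt == ")") {
      "rparen"
    } else if (grepl("^(?:[0-9]|\\.[0-9])", txt)) {
      "num"
    } else if (grepl("^[A-Za-z_]", txt) || txt %in% c("<-", "<->")) {
      "sym"
    } else {
      "op"
    }
    toks[[i]] <- list(kind = kind, text = txt, start = s,
                      end = s + lens[i] - 1L,
                      line = line_of(s), col = col_of(s))
  }
  toks <- Filter(function(t) t$kind != "comment", toks)
  merge_unit_tokens(toks, text)
}

# A unit annotation is an identifier-like token that directly follows a
# numeric literal, separated by blanks only, optionally continued by
# adjacent `/` or `*` and further identifier/integer tokens with no
# intervening space (e.g. `uF/cm*cm`).
merge_unit_tokens <- function(toks, text) {
  out <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    t <- toks[[i]]
    if (t$kind == "num" && i < n) {
      nxt <- toks[[i + 1L]]
      gap <- substr(text, t$end + 1L, nxt$start - 1L)
      if (nxt$kind == "sym" && !nxt$text %in% c("<-", "<->") &&
          nchar(gap) > 0L && grepl("^[ \t]+$", gap)) {
        unit <- nxt$text
        j <- i + 1L
        while (j + 1L < n + 1L && j + 2L <= n) {
          o <- toks[[j + 1L]]
          v <- toks[[j + 2L]]
          if (o$kind == "op" && o$text %in% c("/", "*") &&
              o$start == toks[[j]]$end + 1L &&
              v$start == o$end + 1L && v$kind %in% c("sym", "num")) {
            unit <- paste0(unit, o$text, v$text)
            j <- j + 2L
          } else {
            break
          }
        }
        t$unit <- unit
        out[[length(out) + 1L]] <- t
        i <- j + 1L
        next
      }
    }
    out[[length(out) + 1L]] <- t
    i <- i + 1L
  }
  out
}

## --------------------------------------------------------------- parser ----

#' Parse model source in the parenthesized (s-expression) syntax
#'
#' Reads one datum -- usually a `(Membrane-potential ...)` component -- and
#' returns the syntax tree. Comments introduced by `;` run to the end of the
#' line. Infix arithmetic inside rate and equation bodies is kept as raw
#' token sequences within the tree; the equation layer parses those into
#' expression ASTs (see [parse_expr_node()]).
#'
#' @param text Model source, a single character string (or a character
#'   vector of lines, which is joined with newlines).
#' @return A SyntaxNode (see [write_sexpr()] for the inverse).
#' @examples
#' ast <- parse_sexpr("(const duration = 2000)")
#' write_sexpr(ast)
#' @export
parse_sexpr <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) syntax_error("empty input")
  toks <- tokenize(text)
  if (length(toks) == 0L) syntax_error("empty input")
  pos <- 1L
  read_datum <- function() {
    t <- toks[[pos]]
    if (t$kind == "lparen") {
      open <- t
      pos <<- pos + 1L
      children <- list()
      repeat {
        if (pos > length(toks)) {
          syntax_error("unbalanced parentheses: missing ')'",
                       open$line, open$col)
        }
        if (toks[[pos]]$kind == "rparen") {
          pos <<- pos + 1L
          return(im_node(children))
        }
        children[[length(children) + 1L]] <- read_datum()
      }
    }
    pos <<- pos + 1L
    switch(t$kind,
      num = im_num(as.numeric(t$text),
                   if (is.null(t$unit)) NA_character_ else t$unit),
      sym = im_sym(t$text),
      op = im_op(t$text),
      rparen = syntax_error("unbalanced parentheses: unexpected ')'",
                            t$line, t$col)
    )
  }
  datum <- read_datum()
  if (pos <= length(toks)) {
    t <- toks[[pos]]
    syntax_error(sprintf("stray token '%s' after top-level form",
                         t$text), t$line, t$col)
  }
  datum
}

## --------------------------------------------------------------- writer ----

fmt_number <- function(x) {
  if (is.na(x)) return("NA")
  s <- sprintf("%.15g", x)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}

write_atom <- function(x) {
  switch(x$kind,
    sym = x$name,
    op = x$op,
    num = if (!is.na(x$unit)) paste(fmt_number(x$value), x$unit)
          else fmt_number(x$value),
    stop("not an atom")
  )
}

#' Serialize a syntax tree to canonical s-expression text
#'
#' Deterministic, byte-stable: the same tree always yields identical text,
#' and `parse_sexpr(write_sexpr(x))` reproduces `x`.
#'
#' @param node A SyntaxNode as produced by [parse_sexpr()] or [parse_xml()].
#' @return A character string.
#' @export
write_sexpr <- function(node) {
  wr <- function(x) {
    if (is_node(x)) {
      paste0("(", paste(vapply(x$children, wr, ""), collapse = " "), ")")
    } else {
      write_atom(x)
    }
  }
  wr(node)
}

# Structural equality of syntax trees (numbers compared exactly).
ast_equal <- function(a, b) identical(a, b)
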