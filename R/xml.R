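# XML dialect of the model language. The two formats are completely
# interchangeable: the XML rendering of a model parses to an AST
# element-wise identical to the one produced from the s-expression text.
#
# Mapping: a tree node whose first child is a symbol S (a legal XML name
# not colliding with the atom element names) becomes element <S> holding
# the remaining children; any other node becomes <group> holding all its
# children. Atoms are <sym name=".."/>, <num value=".." [unit=".."]/> and
# <op name=".."/>.

.xml_reserved <- c("group", "sym", "num", "op")

xml_name_ok <- function(nm) {
  grepl("^[A-Za-z_][A-Za-z0-9._-]*$", nm) && !nm %in% .xml_reserved
}

#' Serialize a syntax tree to the XML dialect
#'
#' @param node A SyntaxNode.
#' @return XML text (single character string, with declaration).
#' @seealso [parse_xml()], [write_sexpr()]
#' @export
write_xml <- function(node) {
  doc <- xml2::xml_new_root("model")
  add <- function(parent, x) {
    if (is_node(x)) {
      ch <- x$children
      if (length(ch) >= 1L && is_sym(ch[[1L]]) && xml_name_ok(ch[[1L]]$name)) {
        el <- xml2::xml_add_child(parent, ch[[1L]]$name)
        for (c2 in ch[-1L]) add(el, c2)
      } else {
        el <- xml2::xml_add_child(parent, "group")
        for (c2 in ch) add(el, c2)
      }
    } else if (is_sym(x)) {
      xml2::xml_add_child(parent, "sym", name = x$name)
    } else if (is_num_atom(x)) {
      el <- xml2::xml_add_child(parent, "num", value = fmt_number(x$value))
      if (!is.na(x$unit)) xml2::xml_set_attr(el, "unit", x$unit)
    } else if (is_op_atom(x)) {
      xml2::xml_add_child(parent, "op", name = x$op)
    } else {
      stop("invalid syntax tree")
    }
  }
  add(doc, node)
  as.character(doc)
}

#' Parse model source in the XML dialect
#'
#' Inverse of [write_xml()]: yields an AST element-wise identical to the
#' one [parse_sexpr()] produces from the corresponding s-expression text.
#'
#' @param text XML source (string or lines).
#' @return A SyntaxNode.
#' @export
parse_xml <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) syntax_error("empty XML document")
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    syntax_error(paste0("malformed XML: ", conditionMessage(e)))
  })
  if (!identical(xml2::xml_name(doc), "model")) {
    grammar_error(sprintf("unknown root element '%s' (expected <model>)",
                          xml2::xml_name(doc)))
  }
  kids <- xml2::xml_children(doc)
  if (length(kids) != 1L) {
    grammar_error("the <model> element must hold exactly one form")
  }
  conv <- function(el) {
    nm <- xml2::xml_name(el)
    if (nm == "sym") {
      v <- xml2::xml_attr(el, "name")
      if (is.na(v)) grammar_error("<sym> element without name attribute")
      return(im_sym(v))
    }
    if (nm == "num") {
      v <- xml2::xml_attr(el, "value")
      if (is.na(v) || is.na(suppressWarnings(as.numeric(v)))) {
        grammar_error("<num> element without a numeric value attribute")
      }
      return(im_num(as.numeric(v), xml2::xml_attr(el, "unit")))
    }
    if (nm == "op") {
      v <- xml2::xml_attr(el, "name")
      if (is.na(v)) grammar_error("<op> element without name attribute")
      return(im_op(v))
    }
    children <- lapply(xml2::xml_children(el), conv)
    if (nm == "group") return(im_node(children))
    im_node(c(list(im_sym(nm)), children))
  }
  conv(kids[[1L]])
}
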