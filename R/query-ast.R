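# Common query AST shared by the PubMed and Ovid parsers.
#
# Node kinds:
#   fc_leaf — a text term or descriptor term with a search field
#   fc_bool — AND / OR over >= 2 children; NOT over exactly 2 (A AND NOT B)
#   fc_prox — adjacency between two sides, each one text leaf or a set of
#             alternative text leaves (an OR-group)
#
# Fields use one semantic enum across dialects:
#   ti    title only
#   tiab  title + abstract            (PubMed [tiab]; Ovid .tw)
#   tw    wide text-word scope        (PubMed [tw]: title + abstract +
#         index-term names/subheadings + entry terms)
#   mp    Ovid .mp, same scope as tw
#   ec    Embase classification code, exact string match
#   jn    journal name (never satisfied by any other field)
#   mh    controlled-vocabulary descriptor leaf

FC_TEXT_FIELDS <- c("ti", "tiab", "tw", "mp", "ec", "jn")

new_text_leaf <- function(surface, field, quoted = FALSE) {
  surface <- trimws(surface)
  if (!nzchar(surface)) stop("empty term surface", call. = FALSE)
  structure(
    list(
      kind = "text", surface = surface, field = field,
      truncated = grepl("[$*]$", surface) ||
        any(grepl("[$*]$", tokenize_text(surface, keep = "$*?"))),
      wildcard = grepl("?", surface, fixed = TRUE),
      quoted = isTRUE(quoted)
    ),
    class = c("fc_leaf", "fc_node")
  )
}

new_descriptor_leaf <- function(name, explode, major, subheading = NA_character_,
                                quoted = FALSE) {
  name <- trimws(name)
  if (!nzchar(name)) stop("empty descriptor name", call. = FALSE)
  structure(
    list(
      kind = "descriptor", surface = name, field = "mh",
      explode = isTRUE(explode), major = isTRUE(major),
      subheading = subheading, quoted = isTRUE(quoted)
    ),
    class = c("fc_leaf", "fc_node")
  )
}

new_bool <- function(op, children) {
  op <- toupper(op)
  stopifnot(op %in% c("AND", "OR", "NOT"))
  if (op == "NOT" && length(children) != 2L) {
    stop("NOT takes exactly two operands", call. = FALSE)
  }
  if (op != "NOT" && length(children) < 2L) {
    stop(op, " needs at least two operands", call. = FALSE)
  }
  structure(list(op = op, children = children), class = c("fc_bool", "fc_node"))
}

new_prox <- function(left, right, distance, ordered, field = NA_character_) {
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) stop("adjacency distance must be >= 1", call. = FALSE)
  for (side in list(left, right)) {
    ok <- all(vapply(side, function(l) {
      inherits(l, "fc_leaf") && l$kind == "text"
    }, logical(1)))
    if (!ok || length(side) == 0L) {
      stop("adjacency operands must be text terms or OR-groups of text terms",
           call. = FALSE)
    }
  }
  structure(
    list(left = left, right = right, distance = distance,
         ordered = isTRUE(ordered), field = field),
    class = c("fc_prox", "fc_node")
  )
}

new_query <- function(root, dialect, source_text = NULL) {
  dialect <- match.arg(dialect, c("pubmed", "ovid_medline", "ovid_embase"))
  q <- structure(
    list(root = root, dialect = dialect,
         source_text = source_text %||% render_node(root, dialect)),
    class = "fc_query"
  )
  validate_query_fields(q)
  q
}

validate_query_fields <- function(q) {
  walk_leaves(q$root, function(leaf) {
    if (leaf$kind == "text" && !is.na(leaf$field)) {
      legal <- if (q$dialect == "pubmed") c("tw", "tiab", "ti", "jn")
               else c("mp", "tiab", "ti", "ec", "jn")
      if (!(leaf$field %in% legal)) {
        stop("field '", leaf$field, "' is not legal in dialect ", q$dialect,
             call. = FALSE)
      }
    }
  })
  invisible(q)
}

# Apply fn to every leaf (including proximity alternatives).
walk_leaves <- function(node, fn) {
  if (inherits(node, "fc_leaf")) {
    fn(node)
  } else if (inherits(node, "fc_bool")) {
    for (ch in node$children) walk_leaves(ch, fn)
  } else if (inherits(node, "fc_prox")) {
    for (l in c(node$left, node$right)) fn(l)
  } else {
    stop("unknown query node", call. = FALSE)
  }
  invisible(NULL)
}

#' Count the atomic terms of a query
#'
#' Counts every text term and descriptor term in the tree; each alternative
#' on either side of an adjacency operator counts as one atom (so
#' `(diabetic adj (kidney or renal))` contributes three).
#'
#' @param query An [parse_pubmed()]/[parse_ovid()] query, or a bare node.
#' @return Integer atom count.
#' @examples
#' count_leaves(parse_pubmed("nephrotic[tw] OR (lupus[tw] AND renal[tw])"))
#' @export
count_leaves <- function(query) {
  node <- if (inherits(query, "fc_query")) query$root else query
  count_node <- function(n) {
    if (inherits(n, "fc_leaf")) return(1L)
    if (inherits(n, "fc_prox")) return(length(n$left) + length(n$right))
    sum(vapply(n$children, count_node, integer(1)))
  }
  count_node(node)
}

# ---- structural equality ----------------------------------------------------

node_equal <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (inherits(a, "fc_leaf")) {
    if (a$kind != b$kind || !identical(a$field, b$field)) return(FALSE)
    if (!identical(a$surface, b$surface)) return(FALSE)
    if (a$kind == "descriptor") {
      return(identical(a$explode, b$explode) && identical(a$major, b$major) &&
             identical(a$subheading, b$subheading) && identical(a$quoted, b$quoted))
    }
    return(identical(a$truncated, b$truncated) && identical(a$wildcard, b$wildcard) &&
           identical(a$quoted, b$quoted))
  }
  if (inherits(a, "fc_bool")) {
    if (a$op != b$op || length(a$children) != length(b$children)) return(FALSE)
    return(all(mapply(node_equal, a$children, b$children)))
  }
  if (inherits(a, "fc_prox")) {
    if (a$distance != b$distance || !identical(a$ordered, b$ordered)) return(FALSE)
    if (!identical(a$field, b$field)) return(FALSE)
    if (length(a$left) != length(b$left) || length(a$right) != length(b$right)) return(FALSE)
    return(all(mapply(node_equal, a$left, b$left)) &&
           all(mapply(node_equal, a$right, b$right)))
  }
  FALSE
}

#' Structural (AST) equality of two queries
#'
#' Compares dialect and tree structure; the original source text and
#' redundant parentheses are ignored, child order is significant.
#'
#' @param a,b Queries.
#' @return `TRUE` or `FALSE`.
#' @export
query_equal <- function(a, b) {
  stopifnot(inherits(a, "fc_query"), inherits(b, "fc_query"))
  a$dialect == b$dialect && node_equal(a$root, b$root)
}

# ---- rendering --------------------------------------------------------------

pubmed_tag <- function(leaf) {
  if (leaf$kind == "text") return(leaf$field)
  base <- if (leaf$major) "majr" else "mh"
  if (leaf$explode) base else paste0(base, ":noexp")
}

ovid_suffix <- function(field) {
  switch(field, mp = "mp", tiab = "tw", ti = "ti", ec = "ec", jn = "jn",
         stop("field '", field, "' has no Ovid suffix", call. = FALSE))
}

render_leaf <- function(leaf, dialect) {
  if (dialect == "pubmed") {
    surface <- leaf$surface
    if (leaf$kind == "descriptor" && !is.na(leaf$subheading)) {
      surface <- paste0(surface, "/", leaf$subheading)
    }
    if (leaf$quoted) surface <- paste0('"', surface, '"')
    paste0(surface, "[", pubmed_tag(leaf), "]")
  } else {
    if (leaf$kind == "descriptor") {
      paste0(if (leaf$explode) "exp " else "", if (leaf$major) "*" else "",
             leaf$surface, "/",
             if (!is.na(leaf$subheading)) leaf$subheading else "")
    } else {
      surface <- if (leaf$quoted) paste0('"', leaf$surface, '"') else leaf$surface
      paste0(surface, ".", ovid_suffix(leaf$field))
    }
  }
}

render_prox_side <- function(side) {
  if (length(side) == 1L) return(side[[1L]]$surface)
  paste0("(", paste(vapply(side, `[[`, character(1), "surface"), collapse = " or "), ")")
}

render_node <- function(node, dialect) {
  if (inherits(node, "fc_leaf")) return(render_leaf(node, dialect))
  if (inherits(node, "fc_prox")) {
    adjtok <- if (node$distance == 1L && node$ordered) "adj" else paste0("adj", node$distance)
    core <- paste0("(", render_prox_side(node$left), " ", adjtok, " ",
                   render_prox_side(node$right), ")")
    return(paste0(core, ".", ovid_suffix(node$field)))
  }
  if (inherits(node, "fc_bool")) {
    parts <- vapply(node$children, render_node, character(1), dialect = dialect)
    return(paste0("(", paste(parts, collapse = paste0(" ", node$op, " ")), ")"))
  }
  stop("unknown query node", call. = FALSE)
}

#' Render a query back to dialect-correct text
#'
#' The rendered string reparses (with the same dialect) to a query that is
#' AST-equal to the input; redundant parentheses may be added.
#'
#' @param query An `fc_query`.
#' @return Query string.
#' @export
to_string <- function(query) {
  stopifnot(inherits(query, "fc_query"))
  render_node(query$root, query$dialect)
}

format_ast <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  if (inherits(node, "fc_leaf")) {
    if (node$kind == "descriptor") {
      extras <- paste0(
        "explode=", node$explode, " major=", node$major,
        if (!is.na(node$subheading)) paste0(" subheading=", node$subheading)
      )
      return(paste0(pad, "descriptor \"", node$surface, "\" [", extras, "]"))
    }
    flags <- c(if (node$truncated) "truncated", if (node$wildcard) "wildcard")
    return(paste0(pad, "term \"", node$surface, "\" [", node$field,
                  if (length(flags)) paste0(" ", paste(flags, collapse = ",")), "]"))
  }
  if (inherits(node, "fc_prox")) {
    side <- function(s) paste(vapply(s, `[[`, character(1), "surface"), collapse = " | ")
    return(paste0(pad, "adj", if (node$distance > 1L) node$distance,
                  " [", node$field, "] (", side(node$left), ") ~ (",
                  side(node$right), ")"))
  }
  lines <- paste0(pad, node$op)
  for (ch in node$children) lines <- c(lines, format_ast(ch, indent + 1L))
  lines
}

#' @export
print.fc_query <- function(x, ...) {
  cat(sprintf("<query dialect=%s, %d atoms>\n", x$dialect, count_leaves(x)))
  cat(paste(format_ast(x$root), collapse = "\n"), "\n")
  invisible(x)
}
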