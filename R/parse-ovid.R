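# Ovid-dialect query parser (Ovid Medline and Embase syntax).
#
# Supported syntax:
#   exp Name/        exploded descriptor        *Name/      major-topic
#   exp *Name/       both                        Name/       neither
#   Name/subheading  descriptor with subheading
#   term.mp .tw .ti .ec   suffix search fields (trailing period tolerated,
#                         as in printed strategies: `term.mp.`)
#   glomerulo$       truncation    polyang?itis  zero-or-one-char wildcard
#   a adj b / a adjN b    adjacency; either side may be an OR-group of
#                         terms: (diabetic adj (kidney or renal)).mp
#   AND OR NOT       case-insensitive Boolean operators
#
# A field suffix after a parenthesized group distributes onto every term
# and adjacency node inside it that has no explicit field of its own, the
# way Ovid applies `(x AND y).ti`. Terms with no suffix anywhere default
# to `.mp`. Descriptor names may contain commas ("Lupus Erythematosus,
# Systemic") and hyphens.

OVID_SUFFIX_MAP <- c(mp = "mp", tw = "tiab", ti = "ti", ec = "ec")

ovid_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LP", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RP", ")", i); i <- i + 1L; next }
    if (ch == "/") { push("SLASH", "/", i); i <- i + 1L; next }
    if (ch == ",") { push("COMMA", ",", i); i <- i + 1L; next }
    if (ch == ".") { push("DOT", ".", i); i <- i + 1L; next }
    if (ch == "*") { push("STAR", "*", i); i <- i + 1L; next }
    if (ch == '"') {
      j <- regexpr('"', substr(text, i + 1L, n), fixed = TRUE)
      if (j == -1L) stop("parse error at position ", i, ": unterminated quote", call. = FALSE)
      push("QUOTED", substr(text, i + 1L, i + j - 1L), i)
      i <- i + j + 1L
      next
    }
    m <- regexpr('^[^]["()/,.*[:space:]]+', substr(text, i, n))
    len <- attr(m, "match.length")
    if (len <= 0L) stop("parse error at position ", i, ": unexpected character '", ch, "'",
                        call. = FALSE)
    push("WORD", substr(text, i, i + len - 1L), i)
    i <- i + len
  }
  tokens
}

is_adj_word <- function(tok) {
  !is.null(tok) && tok$type == "WORD" && grepl("^adj[0-9]*$", tolower(tok$value))
}

is_ovid_reserved <- function(tok) {
  is_op_word(tok) || is_adj_word(tok) ||
    (!is.null(tok) && tok$type == "WORD" && tolower(tok$value) == "exp")
}

# field suffix distribution: set `field` on text leaves and adjacency nodes
# that do not yet have one
distribute_field <- function(node, field) {
  if (inherits(node, "fc_leaf")) {
    if (node$kind == "text" && is.na(node$field)) node$field <- field
    return(node)
  }
  if (inherits(node, "fc_prox")) {
    if (is.na(node$field)) node$field <- field
    return(node)
  }
  node$children <- lapply(node$children, distribute_field, field = field)
  node
}

finalize_ovid_fields <- function(node) {
  distribute_field(node, "mp")
}

ovid_collect_name <- function(ts, what) {
  pieces <- character()
  repeat {
    tok <- ts_peek(ts)
    if (!is.null(tok) && tok$type == "WORD" && !is_ovid_reserved(tok)) {
      pieces <- c(pieces, tok$value)
      ts_next(ts)
    } else if (!is.null(tok) && tok$type == "COMMA") {
      if (length(pieces) == 0L) parse_fail(ts, "unexpected ','")
      pieces[length(pieces)] <- paste0(pieces[length(pieces)], ",")
      ts_next(ts)
    } else {
      break
    }
  }
  if (length(pieces) == 0L) parse_fail(ts, paste0("expected ", what))
  paste(pieces, collapse = " ")
}

ovid_parse_descriptor_tail <- function(ts, name, explode, major) {
  sl <- ts_next(ts)
  if (is.null(sl) || sl$type != "SLASH") {
    parse_fail(ts, paste0("expected '/' after descriptor '", name, "'"))
  }
  subheading <- NA_character_
  tok <- ts_peek(ts)
  if (!is.null(tok) && tok$type == "WORD" && !is_ovid_reserved(tok)) {
    subheading <- tok$value
    ts_next(ts)
  }
  new_descriptor_leaf(name, explode = explode, major = major, subheading = subheading)
}

ovid_parse_term <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) parse_fail(ts, "expected a term")
  if (tok$type == "QUOTED") {
    ts_next(ts)
    return(new_text_leaf(tok$value, NA_character_, quoted = TRUE))
  }
  if (tok$type == "WORD" && tolower(tok$value) == "exp") {
    ts_next(ts)
    major <- FALSE
    if (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "STAR") {
      major <- TRUE
      ts_next(ts)
    }
    name <- ovid_collect_name(ts, "a descriptor name after 'exp'")
    return(ovid_parse_descriptor_tail(ts, name, explode = TRUE, major = major))
  }
  if (tok$type == "STAR") {
    ts_next(ts)
    name <- ovid_collect_name(ts, "a descriptor name after '*'")
    return(ovid_parse_descriptor_tail(ts, name, explode = FALSE, major = TRUE))
  }
  if (tok$type != "WORD") parse_fail(ts, paste0("unexpected '", tok$value, "'"))
  phrase <- ovid_collect_name(ts, "a term")
  nxt <- ts_peek(ts)
  if (!is.null(nxt) && nxt$type == "SLASH") {
    return(ovid_parse_descriptor_tail(ts, phrase, explode = FALSE, major = FALSE))
  }
  new_text_leaf(phrase, NA_character_)
}

ovid_parse_suffix <- function(ts, node) {
  # one optional `.field` (with tolerated trailing dot) after a primary;
  # force the node before peeking — its parse must consume tokens first
  force(node)
  tok <- ts_peek(ts)
  if (is.null(tok) || tok$type != "DOT") return(node)
  fld <- ts_peek(ts, 1L)
  if (is.null(fld) || fld$type != "WORD" ||
      !(tolower(fld$value) %in% names(OVID_SUFFIX_MAP))) {
    parse_fail(ts, "expected a field suffix (.mp .tw .ti .ec) after '.'")
  }
  ts_next(ts); ts_next(ts)
  if (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "DOT") ts_next(ts)
  distribute_field(node, OVID_SUFFIX_MAP[[tolower(fld$value)]])
}

ovid_parse_primary <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) parse_fail(ts, "unexpected end of query")
  if (tok$type == "LP") {
    ts_next(ts)
    node <- ovid_parse_or(ts)
    cl <- ts_next(ts)
    if (is.null(cl) || cl$type != "RP") parse_fail(ts, "expected ')'")
    return(ovid_parse_suffix(ts, node))
  }
  if (tok$type == "RP") parse_fail(ts, "unbalanced ')'")
  if (is_op_word(tok) || is_adj_word(tok)) {
    parse_fail(ts, paste0("unexpected operator '", tok$value, "'"))
  }
  ovid_parse_suffix(ts, ovid_parse_term(ts))
}

as_prox_side <- function(node, ts) {
  strip_ok <- function(leaf) {
    inherits(leaf, "fc_leaf") && leaf$kind == "text" && is.na(leaf$field)
  }
  if (inherits(node, "fc_leaf")) {
    if (!strip_ok(node)) {
      parse_fail(ts, "adjacency operands must be unfielded text terms")
    }
    return(list(node))
  }
  if (inherits(node, "fc_bool") && node$op == "OR" &&
      all(vapply(node$children, strip_ok, logical(1)))) {
    return(node$children)
  }
  parse_fail(ts, "adjacency operands must be a term or an OR group of terms")
}

ovid_parse_prox <- function(ts) {
  node <- ovid_parse_primary(ts)
  if (!is_adj_word(ts_peek(ts))) return(node)
  adj <- ts_next(ts)
  spec <- tolower(adj$value)
  if (spec == "adj") {
    distance <- 1L
    ordered <- TRUE
  } else {
    distance <- as.integer(sub("^adj", "", spec))
    if (is.na(distance) || distance < 1L) {
      parse_fail(ts, paste0("invalid adjacency operator '", adj$value, "'"))
    }
    ordered <- distance == 1L
  }
  rhs <- ovid_parse_primary(ts)
  prox <- new_prox(as_prox_side(node, ts), as_prox_side(rhs, ts),
                   distance = distance, ordered = ordered)
  if (is_adj_word(ts_peek(ts))) parse_fail(ts, "chained adjacency is not supported")
  prox
}

ovid_parse_not <- function(ts) {
  node <- ovid_parse_prox(ts)
  while (is_op_word(ts_peek(ts), "not")) {
    ts_next(ts)
    node <- new_bool("NOT", list(node, ovid_parse_prox(ts)))
  }
  node
}

ovid_parse_and <- function(ts) {
  children <- list(ovid_parse_not(ts))
  while (is_op_word(ts_peek(ts), "and")) {
    ts_next(ts)
    children[[length(children) + 1L]] <- ovid_parse_not(ts)
  }
  if (length(children) == 1L) children[[1L]] else new_bool("AND", children)
}

ovid_parse_or <- function(ts) {
  children <- list(ovid_parse_and(ts))
  while (is_op_word(ts_peek(ts), "or")) {
    ts_next(ts)
    children[[length(children) + 1L]] <- ovid_parse_and(ts)
  }
  if (length(children) == 1L) children[[1L]] else new_bool("OR", children)
}

#' Parse an Ovid-dialect query
#'
#' @param text Query string (non-empty).
#' @param dialect `"ovid_medline"` or `"ovid_embase"`.
#' @return An `fc_query`.
#' @examples
#' parse_ovid("exp Kidney Diseases/", "ovid_medline")
#' parse_ovid("(diabetic adj (kidney or renal)).mp", "ovid_medline")
#' @export
parse_ovid <- function(text, dialect = c("ovid_medline", "ovid_embase")) {
  dialect <- match.arg(dialect)
  assert_scalar_chr(text, "query text")
  if (!nzchar(trimws(text))) stop("parse error at position 1: empty query", call. = FALSE)
  ts <- new_token_stream(ovid_tokenize(text), text)
  root <- ovid_parse_or(ts)
  if (!is.null(ts_peek(ts))) parse_fail(ts, "trailing input")
  new_query(finalize_ovid_fields(root), dialect, source_text = text)
}

#' Parse a query in any supported dialect
#'
#' @param text Query string.
#' @param dialect One of `"pubmed"`, `"ovid_medline"`, `"ovid_embase"`.
#' @return An `fc_query`.
#' @export
parse_query <- function(text, dialect = c("pubmed", "ovid_medline", "ovid_embase")) {
  dialect <- match.arg(dialect)
  if (dialect == "pubmed") parse_pubmed(text) else parse_ovid(text, dialect)
}

#' Read a filter file
#'
#' A filter file is UTF-8 text holding one query (possibly spread over
#' several lines). The dialect is declared by a first-line comment
#' `# dialect: pubmed|ovid_medline|ovid_embase`, or passed explicitly.
#'
#' @param path File path.
#' @param dialect Dialect override; if `NULL` the header comment is required.
#' @return An `fc_query`.
#' @export
read_filter_file <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- grepl("^#", lines)
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("dialect:[[:space:]]*([a-z_]+)", h))[[1L]]
    if (length(m) && is.null(dialect)) dialect <- m[2L]
  }
  if (is.null(dialect)) {
    stop("no '# dialect:' header in ", path, " and no dialect given", call. = FALSE)
  }
  text <- paste(lines[!hdr], collapse = " ")
  parse_query(trimws(text), dialect)
}
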