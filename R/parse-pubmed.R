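# PubMed-dialect query parser.
#
# Grammar (operators case-insensitive, OR < AND < NOT precedence, all
# left-associative, parentheses for grouping):
#
#   query   := or
#   or      := and ("OR" and)*
#   and     := not ("AND" not)*
#   not     := primary ("NOT" primary)*          # binary: A NOT B
#   primary := "(" or ")" | term
#   term    := (quoted-phrase | word+) "[" tag "]"
#
# Tags: tw tiab ti jn (text) and mh, mh:noexp, majr, majr:noexp
# (descriptor; [mh]/[majr] explode by default, :noexp turns explosion off,
# majr requires the major-topic flag). `*` at the end of a word means
# truncation. A `/subheading` inside a descriptor name restricts matching
# to index terms carrying that subheading. Every term requires an explicit
# field tag: PubMed's automatic term mapping of untagged terms is out of
# scope, so an untagged term is a parse error rather than silently matching
# nothing.

pubmed_tokenize <- function(text) {
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
    if (ch == '"') {
      j <- regexpr('"', substr(text, i + 1L, n), fixed = TRUE)
      if (j == -1L) stop("parse error at position ", i, ": unterminated quote", call. = FALSE)
      push("QUOTED", substr(text, i + 1L, i + j - 1L), i)
      i <- i + j + 1L
      next
    }
    if (ch == "[") {
      j <- regexpr("]", substr(text, i + 1L, n), fixed = TRUE)
      if (j == -1L) stop("parse error at position ", i, ": unterminated field tag", call. = FALSE)
      push("TAG", substr(text, i + 1L, i + j - 1L), i)
      i <- i + j + 1L
      next
    }
    m <- regexpr('^[^][()"[:space:]]+', substr(text, i, n))
    len <- attr(m, "match.length")
    push("WORD", substr(text, i, i + len - 1L), i)
    i <- i + len
  }
  tokens
}

is_op_word <- function(tok, ops = c("and", "or", "not")) {
  !is.null(tok) && tok$type == "WORD" && tolower(tok$value) %in% ops
}

new_token_stream <- function(tokens, text) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env$text <- text
  env
}

ts_peek <- function(ts, offset = 0L) {
  k <- ts$i + offset
  if (k > length(ts$tokens)) NULL else ts$tokens[[k]]
}

ts_next <- function(ts) {
  tok <- ts_peek(ts)
  ts$i <- ts$i + 1L
  tok
}

ts_pos <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) nchar(ts$text) + 1L else tok$pos
}

parse_fail <- function(ts, msg) {
  stop("parse error at position ", ts_pos(ts), ": ", msg, call. = FALSE)
}

make_pubmed_leaf <- function(surface, tag, quoted, ts) {
  tag_l <- tolower(gsub("[[:space:]]", "", tag))
  text_fields <- c(tw = "tw", tiab = "tiab", ti = "ti", jn = "jn")
  if (tag_l %in% names(text_fields)) {
    return(new_text_leaf(surface, text_fields[[tag_l]], quoted = quoted))
  }
  m <- regmatches(tag_l, regexec("^(mh|majr)(:noexp)?$", tag_l))[[1L]]
  if (length(m) == 0L) parse_fail(ts, paste0("unknown field tag [", tag, "]"))
  name <- surface
  subheading <- NA_character_
  if (grepl("/", surface, fixed = TRUE)) {
    parts <- strsplit(surface, "/", fixed = TRUE)[[1L]]
    name <- parts[1L]
    subheading <- trimws(parts[2L])
  }
  new_descriptor_leaf(name, explode = !nzchar(m[3L]), major = m[2L] == "majr",
                      subheading = subheading, quoted = quoted)
}

pubmed_parse_term <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) parse_fail(ts, "expected a term")
  if (tok$type == "QUOTED") {
    ts_next(ts)
    phrase <- tok$value
    quoted <- TRUE
  } else if (tok$type == "WORD") {
    words <- character()
    while (!is.null(tok <- ts_peek(ts)) && tok$type == "WORD" && !is_op_word(tok)) {
      words <- c(words, tok$value)
      ts_next(ts)
    }
    if (length(words) == 0L) parse_fail(ts, "expected a term")
    phrase <- paste(words, collapse = " ")
    quoted <- FALSE
  } else {
    parse_fail(ts, paste0("unexpected '", tok$value, "'"))
  }
  tag <- ts_peek(ts)
  if (is.null(tag) || tag$type != "TAG") {
    parse_fail(ts, paste0("term '", phrase, "' requires a field tag like [tw]"))
  }
  ts_next(ts)
  make_pubmed_leaf(phrase, tag$value, quoted, ts)
}

pubmed_parse_primary <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) parse_fail(ts, "unexpected end of query")
  if (tok$type == "LP") {
    ts_next(ts)
    node <- pubmed_parse_or(ts)
    cl <- ts_next(ts)
    if (is.null(cl) || cl$type != "RP") parse_fail(ts, "expected ')'")
    return(node)
  }
  if (tok$type == "RP") parse_fail(ts, "unbalanced ')'")
  if (is_op_word(tok)) parse_fail(ts, paste0("unexpected operator '", tok$value, "'"))
  pubmed_parse_term(ts)
}

pubmed_parse_not <- function(ts) {
  node <- pubmed_parse_primary(ts)
  while (is_op_word(ts_peek(ts), "not")) {
    ts_next(ts)
    rhs <- pubmed_parse_primary(ts)
    node <- new_bool("NOT", list(node, rhs))
  }
  node
}

pubmed_parse_and <- function(ts) {
  children <- list(pubmed_parse_not(ts))
  while (is_op_word(ts_peek(ts), "and")) {
    ts_next(ts)
    children[[length(children) + 1L]] <- pubmed_parse_not(ts)
  }
  if (length(children) == 1L) children[[1L]] else new_bool("AND", children)
}

pubmed_parse_or <- function(ts) {
  children <- list(pubmed_parse_and(ts))
  while (is_op_word(ts_peek(ts), "or")) {
    ts_next(ts)
    children[[length(children) + 1L]] <- pubmed_parse_and(ts)
  }
  if (length(children) == 1L) children[[1L]] else new_bool("OR", children)
}

#' Parse a PubMed-dialect query
#'
#' @param text Query string (non-empty).
#' @return An `fc_query` with dialect `"pubmed"`.
#' @examples
#' parse_pubmed("Kidney Diseases[mh]")
#' parse_pubmed('"Kidney Glomerulus"[majr:noexp] OR nephropath*[tw]')
#' @export
parse_pubmed <- function(text) {
  assert_scalar_chr(text, "query text")
  if (!nzchar(trimws(text))) stop("parse error at position 1: empty query", call. = FALSE)
  ts <- new_token_stream(pubmed_tokenize(text), text)
  root <- pubmed_parse_or(ts)
  if (!is.null(ts_peek(ts))) parse_fail(ts, "trailing input")
  new_query(root, "pubmed", source_text = text)
}
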