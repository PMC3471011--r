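# Tokenization shared by the evaluator and the synthetic generator.
#
# Citation text and query phrases are lowercased and split on whitespace and
# hyphens; all other punctuation is stripped. Splitting on hyphens makes
# "anti-glomerular" a two-token phrase, so the hyphenated and open forms of a
# compound term match each other, while closed forms ("antiglomerular")
# remain distinct search terms.

#' Tokenize citation text
#'
#' @param x Character scalar (title, abstract, index-term string, ...).
#' @param keep Extra characters to preserve inside tokens; query phrases keep
#'   the truncation and wildcard markers `$`, `*`, `?`.
#' @return Character vector of tokens (possibly empty).
#' @keywords internal
tokenize_text <- function(x, keep = "") {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(character())
  x <- tolower(x)
  x <- gsub("[-\u2010\u2011\u2013\u2014/[:space:]]+", " ", x)
  rx <- sprintf("[^a-z0-9 %s]", gsub("([*?$])", "\\\\\\1", keep))
  x <- gsub(rx, "", x)
  x <- trimws(x)
  if (!nzchar(x)) return(character())
  strsplit(x, " +", fixed = FALSE)[[1L]]
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", x)

# Compile a query phrase into per-token matchers. A trailing `$` or `*` on a
# token means prefix match for that token; `?` inside a token matches zero or
# one character at its position.
compile_phrase <- function(surface) {
  toks <- tokenize_text(surface, keep = "$*?")
  if (length(toks) == 0L) stop("empty term surface", call. = FALSE)
  lapply(toks, function(tk) {
    trunc <- grepl("[$*]$", tk)
    core <- gsub("[$*]", "", tk)
    if (grepl("?", core, fixed = TRUE)) {
      rx <- paste0("^", gsub("\\\\\\?", ".?", escape_regex(core)),
                   if (trunc) ".*", "$")
      list(type = "regex", value = rx)
    } else if (trunc) {
      list(type = "prefix", value = core)
    } else {
      list(type = "exact", value = core)
    }
  })
}

match_token_part <- function(tokens, part) {
  switch(part$type,
    exact  = tokens == part$value,
    prefix = startsWith(tokens, part$value),
    regex  = grepl(part$value, tokens)
  )
}

# Start positions (1-based) at which the compiled phrase occurs as
# consecutive tokens of `tokens`.
phrase_starts <- function(tokens, compiled) {
  m <- length(compiled)
  n <- length(tokens)
  if (n < m || m == 0L) return(integer())
  ok <- which(match_token_part(tokens, compiled[[1L]]))
  ok <- ok[ok <= n - m + 1L]
  if (m > 1L) {
    for (k in 2L:m) {
      if (length(ok) == 0L) break
      ok <- ok[match_token_part(tokens[ok + k - 1L], compiled[[k]])]
    }
  }
  ok
}

# All (start, end) occurrences of a phrase in a token vector.
phrase_occurrences <- function(tokens, compiled) {
  s <- phrase_starts(tokens, compiled)
  cbind(start = s, end = s + length(compiled) - 1L)
}
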