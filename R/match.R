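# Query evaluation against citation records.
#
# Field scopes (token sequences searched, per leaf field):
#   ti          title
#   tiab / .tw  title, abstract
#   tw / .mp    title, abstract, index-term descriptor names, subheadings,
#               and entry-term synonym strings (each its own sequence, so
#               phrases never straddle two strings)
#   jn          journal name only; the journal name is deliberately absent
#               from every other scope, so a term appearing solely in the
#               journal name never satisfies a text-word search
#   ec          classification codes, exact (case-insensitive) string match

#' Build the token index of a citation record
#'
#' Precomputes the token sequences every field scope searches. [retrieve()]
#' builds this once per record; [matches()] accepts a prebuilt index via the
#' `index` argument.
#'
#' @param record A [citation_record()].
#' @return A list of token sequences, classed `citation_index`.
#' @keywords internal
citation_token_index <- function(record) {
  idx_seqs <- c(
    lapply(record$index_terms, function(it) tokenize_text(it$descriptor)),
    unlist(lapply(record$index_terms, function(it) {
      lapply(it$subheadings, tokenize_text)
    }), recursive = FALSE),
    lapply(record$entry_term_strings, tokenize_text)
  )
  idx_seqs <- idx_seqs[vapply(idx_seqs, length, integer(1)) > 0L]
  structure(
    list(
      title = tokenize_text(record$title),
      abstract = tokenize_text(record$abstract),
      indexing = idx_seqs,
      journal = tokenize_text(record$journal_id),
      codes = tolower(trimws(record$classification_codes)),
      index_terms = record$index_terms
    ),
    class = "citation_index"
  )
}

scope_sequences <- function(idx, field) {
  switch(field,
    ti = list(idx$title),
    tiab = list(idx$title, idx$abstract),
    tw = ,
    mp = c(list(idx$title, idx$abstract), idx$indexing),
    jn = list(idx$journal),
    stop("no token scope for field '", field, "'", call. = FALSE)
  )
}

# ---- query preparation ------------------------------------------------------

# Precompile phrase matchers and resolve descriptor leaves against the
# thesaurus once per query, so per-record evaluation is cheap.
prepare_node <- function(node, thesaurus) {
  if (inherits(node, "fc_leaf")) {
    if (node$kind == "text") {
      if (!identical(node$field, "ec")) node$compiled <- compile_phrase(node$surface)
      return(node)
    }
    if (is.null(thesaurus)) {
      stop("a thesaurus is required to evaluate descriptor term '",
           node$surface, "'", call. = FALSE)
    }
    canonical <- resolve_descriptor(thesaurus, node$surface)
    node$name_set <- tolower(
      if (node$explode) descendants(thesaurus, canonical) else canonical
    )
    return(node)
  }
  if (inherits(node, "fc_prox")) {
    node$left <- lapply(node$left, function(l) {
      l$compiled <- compile_phrase(l$surface); l
    })
    node$right <- lapply(node$right, function(l) {
      l$compiled <- compile_phrase(l$surface); l
    })
    return(node)
  }
  node$children <- lapply(node$children, prepare_node, thesaurus = thesaurus)
  node
}

eval_text_leaf <- function(leaf, idx) {
  if (identical(leaf$field, "ec")) {
    return(tolower(trimws(leaf$surface)) %in% idx$codes)
  }
  for (seq in scope_sequences(idx, leaf$field)) {
    if (length(phrase_starts(seq, leaf$compiled))) return(TRUE)
  }
  FALSE
}

eval_descriptor_leaf <- function(leaf, idx) {
  for (it in idx$index_terms) {
    if (!(tolower(it$descriptor) %in% leaf$name_set)) next
    if (leaf$major && !it$major) next
    if (!is.na(leaf$subheading) &&
        !(tolower(leaf$subheading) %in% tolower(it$subheadings))) next
    return(TRUE)
  }
  FALSE
}

side_occurrences <- function(side, tokens) {
  occ <- lapply(side, function(l) phrase_occurrences(tokens, l$compiled))
  do.call(rbind, occ)
}

prox_pair_ok <- function(locc, rocc, distance, ordered) {
  for (i in seq_len(nrow(locc))) {
    gap_fwd <- rocc[, "start"] - locc[i, "end"]
    if (ordered) {
      if (any(gap_fwd == 1L)) return(TRUE)
    } else {
      gap_bwd <- locc[i, "start"] - rocc[, "end"]
      if (any(gap_fwd >= 1L & gap_fwd <= distance) ||
          any(gap_bwd >= 1L & gap_bwd <= distance)) return(TRUE)
    }
  }
  FALSE
}

eval_prox <- function(node, idx) {
  for (tokens in scope_sequences(idx, node$field)) {
    locc <- side_occurrences(node$left, tokens)
    if (is.null(locc) || nrow(locc) == 0L) next
    rocc <- side_occurrences(node$right, tokens)
    if (is.null(rocc) || nrow(rocc) == 0L) next
    if (prox_pair_ok(locc, rocc, node$distance, node$ordered)) return(TRUE)
  }
  FALSE
}

eval_node <- function(node, idx) {
  if (inherits(node, "fc_leaf")) {
    if (node$kind == "text") return(eval_text_leaf(node, idx))
    return(eval_descriptor_leaf(node, idx))
  }
  if (inherits(node, "fc_prox")) return(eval_prox(node, idx))
  switch(node$op,
    OR = {
      for (ch in node$children) if (eval_node(ch, idx)) return(TRUE)
      FALSE
    },
    AND = {
      for (ch in node$children) if (!eval_node(ch, idx)) return(FALSE)
      TRUE
    },
    NOT = eval_node(node$children[[1L]], idx) && !eval_node(node$children[[2L]], idx)
  )
}

#' Does a query match a citation record?
#'
#' Evaluates the query's Boolean/adjacency structure over the record's
#' token sequences and index terms. Phrases must occur as consecutive
#' tokens within one field string; `adj` requires the left term immediately
#' before the right term; `adjN` allows up to `N - 1` intervening tokens in
#' either order. Descriptor leaves match when some index term's descriptor
#' lies in the leaf's (exploded) descriptor set, with the major-topic flag
#' and subheading respected when required.
#'
#' @param query An `fc_query`.
#' @param record A [citation_record()].
#' @param thesaurus A [thesaurus()]; required when the query contains
#'   descriptor terms (error if one cannot be resolved).
#' @param index Optional prebuilt [citation_token_index()] of `record`.
#' @return `TRUE` or `FALSE`.
#' @export
matches <- function(query, record, thesaurus = NULL, index = NULL) {
  stopifnot(inherits(query, "fc_query"))
  prepared <- prepare_node(query$root, thesaurus)
  eval_node(prepared, index %||% citation_token_index(record))
}

#' Retrieve the records matching a query
#'
#' @param query An `fc_query`.
#' @param corpus A [labeled_corpus()].
#' @param thesaurus A [thesaurus()] (required for descriptor terms).
#' @return Character vector of matching uids (corpus order).
#' @export
retrieve <- function(query, corpus, thesaurus = NULL) {
  stopifnot(inherits(query, "fc_query"), inherits(corpus, "labeled_corpus"))
  prepared <- prepare_node(query$root, thesaurus)
  idx <- corpus_index(corpus)
  hits <- vapply(idx, function(ix) eval_node(prepared, ix), logical(1))
  corpus_uids(corpus)[hits]
}

# Cache the per-record token indexes on the corpus object's environment-free
# structure: recompute on demand but allow callers in hot loops to reuse.
corpus_index <- function(corpus) {
  lapply(corpus$records, citation_token_index)
}

#' Retrieve with a prebuilt corpus index
#'
#' Hot-loop variant of [retrieve()] for screening many candidate queries
#' against one corpus: build the index once with
#' `lapply(corpus$records, citation_token_index)` and reuse it.
#'
#' @param query An `fc_query`.
#' @param corpus A [labeled_corpus()].
#' @param index List of [citation_token_index()] objects aligned to the
#'   corpus records.
#' @param thesaurus A [thesaurus()] or `NULL`.
#' @return Logical vector over corpus records.
#' @keywords internal
retrieve_mask <- function(query, corpus, index, thesaurus = NULL) {
  prepared <- prepare_node(query$root, thesaurus)
  vapply(index, function(ix) eval_node(prepared, ix), logical(1), USE.NAMES = FALSE)
}
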