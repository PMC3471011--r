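# Independent oracle evaluator: per-leaf uid sets computed by regex scans
# over whitespace-joined token strings, Boolean nodes by set algebra, and
# adjacency by exhaustive token-pair scanning. Deliberately a different
# mechanism from the package evaluator.

oracle_tokens <- function(x) filtercraft:::tokenize_text(x)

# scope strings per record; separate index strings joined with " | " so a
# phrase regex (which uses single spaces) can never straddle two strings
oracle_corpus_strings <- function(corpus) {
  recs <- corpus$records
  join <- function(parts) paste(parts, collapse = " | ")
  list(
    uids = corpus_uids(corpus),
    ti = vapply(recs, function(r) paste(oracle_tokens(r$title), collapse = " "), character(1)),
    tiab = vapply(recs, function(r) {
      join(c(paste(oracle_tokens(r$title), collapse = " "),
             paste(oracle_tokens(r$abstract), collapse = " ")))
    }, character(1)),
    tw = vapply(recs, function(r) {
      ix <- c(
        vapply(r$index_terms, function(it) paste(oracle_tokens(it$descriptor), collapse = " "), character(1)),
        unlist(lapply(r$index_terms, function(it) {
          vapply(it$subheadings, function(s) paste(oracle_tokens(s), collapse = " "), character(1))
        })),
        vapply(r$entry_term_strings, function(s) paste(oracle_tokens(s), collapse = " "), character(1))
      )
      join(c(paste(oracle_tokens(r$title), collapse = " "),
             paste(oracle_tokens(r$abstract), collapse = " "), ix))
    }, character(1)),
    jn = vapply(recs, function(r) paste(oracle_tokens(r$journal_id), collapse = " "), character(1)),
    codes = lapply(recs, function(r) tolower(trimws(r$classification_codes))),
    records = recs
  )
}

oracle_token_regex <- function(token) {
  trunc <- grepl("[$*]$", token)
  core <- gsub("[$*]", "", token)
  chars <- strsplit(core, "")[[1L]]
  rx <- paste(vapply(chars, function(ch) {
    if (ch == "?") ".?" else if (grepl("[a-z0-9]", ch)) ch else paste0("\\", ch)
  }, character(1)), collapse = "")
  if (trunc) rx <- paste0(rx, "[^ ]*")
  rx
}

oracle_phrase_regex <- function(surface) {
  toks <- filtercraft:::tokenize_text(surface, keep = "$*?")
  paste0("(^| )", paste(vapply(toks, oracle_token_regex, character(1)),
                        collapse = " "), "( |$)")
}

oracle_explode <- function(th, name) {
  canonical <- lookup_descriptor(th, name)
  stopifnot(!is.null(canonical))
  roots <- th$descriptors[[canonical]]$tree_numbers
  hits <- names(Filter(function(d) {
    any(outer(d$tree_numbers, paste0(roots, "."), startsWith))
  }, th$descriptors))
  unique(c(canonical, hits))
}

oracle_leaf_uids <- function(leaf, strs, th) {
  if (leaf$kind == "descriptor") {
    set <- tolower(if (leaf$explode) oracle_explode(th, leaf$surface)
                   else lookup_descriptor(th, leaf$surface))
    hit <- vapply(strs$records, function(r) {
      any(vapply(r$index_terms, function(it) {
        tolower(it$descriptor) %in% set &&
          (!leaf$major || it$major) &&
          (is.na(leaf$subheading) ||
             tolower(leaf$subheading) %in% tolower(it$subheadings))
      }, logical(1)))
    }, logical(1))
    return(strs$uids[hit])
  }
  if (identical(leaf$field, "ec")) {
    key <- tolower(trimws(leaf$surface))
    hit <- vapply(strs$codes, function(cc) key %in% cc, logical(1))
    return(strs$uids[hit])
  }
  rx <- oracle_phrase_regex(leaf$surface)
  fld <- if (identical(leaf$field, "mp")) "tw" else leaf$field
  strs$uids[grepl(rx, strs[[fld]])]
}

# exhaustive token-pair adjacency scan
oracle_prox_uids <- function(node, strs, th) {
  side_positions <- function(side, tokens) {
    out <- NULL
    for (alt in side) {
      parts <- vapply(filtercraft:::tokenize_text(alt$surface, keep = "$*?"),
                      oracle_token_regex, character(1))
      m <- length(parts)
      if (length(tokens) < m) next
      for (s in seq_len(length(tokens) - m + 1L)) {
        ok <- TRUE
        for (k in seq_len(m)) {
          if (!grepl(paste0("^", parts[k], "$"), tokens[s + k - 1L])) { ok <- FALSE; break }
        }
        if (ok) out <- rbind(out, c(s, s + m - 1L))
      }
    }
    out
  }
  seqs_for <- function(r) {
    switch(node$field,
      ti = list(oracle_tokens(r$title)),
      tiab = list(oracle_tokens(r$title), oracle_tokens(r$abstract)),
      mp = ,
      tw = c(list(oracle_tokens(r$title), oracle_tokens(r$abstract)),
             lapply(r$index_terms, function(it) oracle_tokens(it$descriptor)),
             unlist(lapply(r$index_terms, function(it) lapply(it$subheadings, oracle_tokens)),
                    recursive = FALSE),
             lapply(r$entry_term_strings, oracle_tokens))
    )
  }
  hit <- vapply(strs$records, function(r) {
    for (tokens in seqs_for(r)) {
      lp <- side_positions(node$left, tokens)
      if (is.null(lp)) next
      rp <- side_positions(node$right, tokens)
      if (is.null(rp)) next
      for (i in seq_len(nrow(lp))) for (j in seq_len(nrow(rp))) {
        fwd <- rp[j, 1L] - lp[i, 2L]
        bwd <- lp[i, 1L] - rp[j, 2L]
        if (node$ordered) {
          if (fwd == 1L) return(TRUE)
        } else if ((fwd >= 1L && fwd <= node$distance) ||
                   (bwd >= 1L && bwd <= node$distance)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  strs$uids[hit]
}

oracle_node_uids <- function(node, strs, th) {
  if (inherits(node, "fc_leaf")) return(oracle_leaf_uids(node, strs, th))
  if (inherits(node, "fc_prox")) return(oracle_prox_uids(node, strs, th))
  sets <- lapply(node$children, oracle_node_uids, strs = strs, th = th)
  switch(node$op,
    OR = Reduce(union, sets),
    AND = Reduce(intersect, sets),
    NOT = setdiff(sets[[1L]], sets[[2L]])
  )
}

oracle_retrieve <- function(query, corpus, th, strs = NULL) {
  strs <- strs %||% oracle_corpus_strings(corpus)
  sort(oracle_node_uids(query$root, strs, th))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive enumeration of OR-of-clause filters (clauses: atoms and,
# optionally, AND pairs) up to max_clauses; returns the best objective value
exhaustive_best <- function(masks, labels, max_clauses = 3L, allow_and = TRUE,
                            objective = function(se, sp) se + sp - 1) {
  clause_masks <- masks
  if (allow_and && length(masks) >= 2L) {
    for (i in seq_along(masks)) for (j in seq_along(masks)) {
      if (i < j) clause_masks <- c(clause_masks, list(masks[[i]] & masks[[j]]))
    }
  }
  n_rel <- sum(labels)
  n_irr <- sum(!labels)
  best <- -Inf
  idx <- seq_along(clause_masks)
  for (k in seq_len(max_clauses)) {
    for (combo in utils::combn(idx, k, simplify = FALSE)) {
      m <- Reduce(`|`, clause_masks[combo])
      se <- sum(m & labels) / n_rel
      sp <- sum(!m & !labels) / n_irr
      best <- max(best, objective(se, sp))
    }
  }
  best
}
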