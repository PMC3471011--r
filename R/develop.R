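# Candidate enumeration, screening, and Boolean combination of single-term
# filters into multi-term filters.
#
# The combiner is a beam search over filters of the shape every published
# topic filter takes: a large OR whose clauses are single atoms or two-way
# conjunctions (optionally exclusions). Growing the OR pushes sensitivity
# up; AND-refining or NOT-excluding a clause pushes specificity up.

#' Describe a candidate search term
#'
#' @param base Term string (free text) or descriptor name.
#' @param has_descriptor Does `base` name a controlled-vocabulary
#'   descriptor (enabling descriptor variants)?
#' @param fields Search fields for the free-text variants, e.g.
#'   `c("tw", "tiab", "ti")` (PubMed) or `c("mp", "tiab", "ti")` (Ovid;
#'   `"tw"` is mapped to `"mp"` for Ovid dialects).
#' @param truncation Also generate a truncated-at-stem variant?
#' @param stem Explicit stem for the truncated variant; when `NULL` a
#'   minimal heuristic strips a trailing "s", then a trailing "y" or "ic",
#'   from the final token (stems shorter than four characters are left
#'   alone).
#' @return Object of class `candidate_term`.
#' @export
candidate_term <- function(base, has_descriptor = FALSE, fields = "tw",
                           truncation = TRUE, stem = NULL) {
  assert_scalar_chr(base, "base")
  if (!isTRUE(has_descriptor) && length(fields) == 0L && !isTRUE(truncation)) {
    stop("candidate term '", base, "' enables no variant axis", call. = FALSE)
  }
  structure(
    list(base = base, has_descriptor = isTRUE(has_descriptor),
         fields = as.character(fields), truncation = isTRUE(truncation),
         stem = stem),
    class = "candidate_term"
  )
}

stem_token <- function(token) {
  out <- sub("s$", "", token)
  if (nchar(out) > 5L) out <- sub("(ic|y)$", "", out)
  if (nchar(out) < 4L) token else out
}

truncated_surface <- function(base, stem, dialect) {
  toks <- tokenize_text(base, keep = "$*?")
  mark <- if (dialect == "pubmed") "*" else "$"
  toks[length(toks)] <- paste0(stem %||% stem_token(toks[length(toks)]), mark)
  paste(toks, collapse = " ")
}

#' Enumerate the query variants of candidate terms
#'
#' Free-text terms produce one query per allowed field, plus a
#' truncated-at-stem variant per field when truncation is enabled.
#' Descriptor terms additionally produce the four descriptor variants:
#' \{plain, major\} x \{exploded, unexploded\}. Duplicate queries (identical
#' canonical form) are removed.
#'
#' @param terms List of [candidate_term()] objects (may be empty).
#' @param dialect Target dialect.
#' @param thesaurus A [thesaurus()]; required for descriptor terms (a
#'   descriptor term whose base is absent from it is an error).
#' @return List of single-leaf `fc_query` objects.
#' @export
enumerate_variants <- function(terms, dialect = c("pubmed", "ovid_medline", "ovid_embase"),
                               thesaurus = NULL) {
  dialect <- match.arg(dialect)
  out <- list()
  add <- function(root) {
    out[[length(out) + 1L]] <<- new_query(root, dialect)
  }
  for (term in terms) {
    stopifnot(inherits(term, "candidate_term"))
    fields <- term$fields
    if (dialect != "pubmed") fields[fields == "tw"] <- "mp"
    if (dialect == "pubmed") fields[fields == "mp"] <- "tw"
    for (f in unique(fields)) {
      add(new_text_leaf(term$base, f))
      if (term$truncation) {
        add(new_text_leaf(truncated_surface(term$base, term$stem, dialect), f))
      }
    }
    if (term$has_descriptor) {
      if (is.null(thesaurus)) {
        stop("descriptor term '", term$base, "' requires a thesaurus", call. = FALSE)
      }
      canonical <- resolve_descriptor(thesaurus, term$base)
      for (explode in c(TRUE, FALSE)) {
        for (major in c(FALSE, TRUE)) {
          add(new_descriptor_leaf(canonical, explode = explode, major = major))
        }
      }
    }
  }
  keys <- vapply(out, to_string, character(1))
  out[!duplicated(keys)]
}

#' Read a candidate-term list from TSV
#'
#' Columns: base, has_descriptor (true/false), fields (comma- or
#' semicolon-separated), truncation (true/false). Lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @return List of [candidate_term()] objects.
#' @export
read_term_list <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("base", "has_descriptor", "fields", "truncation"),
                           fill = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    candidate_term(
      base = tab$base[i],
      has_descriptor = tolower(tab$has_descriptor[i]) %in% c("true", "1", "yes"),
      fields = trimws(strsplit(tab$fields[i], "[,;]")[[1L]]),
      truncation = tolower(tab$truncation[i]) %in% c("true", "1", "yes")
    )
  })
}

#' Configuration for filter development
#'
#' @param objective `"balanced_youden"` (maximize sensitivity +
#'   specificity - 1), `"max_sens_given_spec"` (maximize sensitivity among
#'   states with specificity >= `spec_floor`), or `"max_spec_given_sens"`.
#' @param sens_floor,spec_floor Floors in \[0, 1\] for the constrained
#'   objectives.
#' @param beam_width Number of states kept per beam step (>= 1).
#' @param max_or_clauses Maximum number of OR clauses in a filter.
#' @param allow_and_refinement Allow replacing a clause by a two-way
#'   conjunction (specificity direction).
#' @param allow_not Allow replacing a clause by clause-NOT-atom. Off by
#'   default: published topic filters use OR and AND almost exclusively.
#' @param screen_min_sens,screen_min_spec Single-term screening keeps a
#'   candidate when sensitivity >= `screen_min_sens` OR specificity >=
#'   `screen_min_spec` (defaults keep broadly sensitive terms and highly
#'   specific ones).
#' @param epsilon Minimum objective improvement to continue (> 0).
#' @param seed Integer seed recorded with the run (the search itself is
#'   deterministic).
#' @return Object of class `develop_config`.
#' @export
develop_config <- function(objective = c("balanced_youden", "max_sens_given_spec",
                                         "max_spec_given_sens"),
                           sens_floor = 0, spec_floor = 0, beam_width = 10L,
                           max_or_clauses = 10L, allow_and_refinement = TRUE,
                           allow_not = FALSE, screen_min_sens = 0.10,
                           screen_min_spec = 0.90, epsilon = 1e-4, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(sens_floor >= 0, sens_floor <= 1, spec_floor >= 0, spec_floor <= 1,
            beam_width >= 1, max_or_clauses >= 1, epsilon > 0)
  structure(
    list(objective = objective, sens_floor = sens_floor, spec_floor = spec_floor,
         beam_width = as.integer(beam_width),
         max_or_clauses = as.integer(max_or_clauses),
         allow_and_refinement = isTRUE(allow_and_refinement),
         allow_not = isTRUE(allow_not),
         screen_min_sens = screen_min_sens, screen_min_spec = screen_min_spec,
         epsilon = epsilon, seed = as.integer(seed)),
    class = "develop_config"
  )
}

new_filter_candidate <- function(query, table, perf) {
  structure(list(query = query, table = table, performance = perf),
            class = "filter_candidate")
}

#' @export
print.filter_candidate <- function(x, ...) {
  cat(to_string(x$query), "\n")
  cat(sprintf("  se %s%%  sp %s%%  ppv %s%%  acc %s%%  (a=%d b=%d c=%d d=%d)\n",
              format_percent(x$performance$sensitivity$estimate),
              format_percent(x$performance$specificity$estimate),
              format_percent(x$performance$precision$estimate),
              format_percent(x$performance$accuracy$estimate),
              x$table$a, x$table$b, x$table$c, x$table$d))
  invisible(x)
}

mask_candidate <- function(query, mask, labels, ci_method = "wald", level = 0.95) {
  table <- contingency_table(
    a = sum(mask & labels), b = sum(mask & !labels),
    c = sum(!mask & labels), d = sum(!mask & !labels)
  )
  new_filter_candidate(query, table, performance(table, ci_method, level))
}

#' Evaluate one filter against a labeled corpus
#'
#' Runs retrieval, builds the contingency table, and computes performance.
#' This is the single entry point meant for the validation view: the
#' development loop never touches validation data, so evaluating a selected
#' filter on it once gives an unbiased estimate.
#'
#' @param query An `fc_query`.
#' @param corpus A fully labeled [labeled_corpus()].
#' @param thesaurus A [thesaurus()] or `NULL`.
#' @param ci_method,level Passed to [performance()].
#' @return A `filter_candidate`.
#' @export
evaluate_filter <- function(query, corpus, thesaurus = NULL,
                            ci_method = "wald", level = 0.95) {
  table <- contingency(retrieve(query, corpus, thesaurus), corpus)
  new_filter_candidate(query, table, performance(table, ci_method, level))
}

#' Screen single-term candidates against a labeled corpus
#'
#' Evaluates every candidate query, drops those failing both screening
#' thresholds, and sorts survivors by Youden index (ties: fewer atoms,
#' then query text).
#'
#' @param candidates List of `fc_query` objects (e.g. from
#'   [enumerate_variants()]).
#' @param corpus A fully labeled [labeled_corpus()].
#' @param thesaurus A [thesaurus()] or `NULL`.
#' @param config A [develop_config()].
#' @return List of `filter_candidate` objects, best first.
#' @export
screen <- function(candidates, corpus, thesaurus = NULL, config = develop_config()) {
  labels <- corpus_labels(corpus)
  index <- corpus_index(corpus)
  cands <- lapply(candidates, function(q) {
    mask <- retrieve_mask(q, corpus, index, thesaurus)
    mask_candidate(q, mask, labels)
  })
  keep <- vapply(cands, function(cd) {
    se <- cd$performance$sensitivity$estimate
    sp <- cd$performance$specificity$estimate
    (!is.na(se) && se >= config$screen_min_sens) ||
      (!is.na(sp) && sp >= config$screen_min_spec)
  }, logical(1))
  sort_candidates(cands[keep])
}

sort_candidates <- function(cands) {
  if (length(cands) == 0L) return(cands)
  y <- vapply(cands, function(cd) youden(cd$performance), numeric(1))
  nl <- vapply(cands, function(cd) count_leaves(cd$query), integer(1))
  txt <- vapply(cands, function(cd) to_string(cd$query), character(1))
  cands[order(-y, nl, txt, method = "radix")]
}

# ---- beam search ------------------------------------------------------------

# Clause bookkeeping: each clause is an atom, an (atom AND atom)
# conjunction, or an (atom NOT atom) exclusion, represented by its
# retrieval mask and its query node.
clause_atom <- function(i, atoms) {
  list(key = sprintf("a%03d", i), mask = atoms$masks[[i]],
       node = atoms$queries[[i]]$root, nleaves = atoms$nleaves[[i]])
}

clause_and <- function(i, j, atoms) {
  ij <- sort(c(i, j))
  list(key = sprintf("c%03d&%03d", ij[1L], ij[2L]),
       mask = atoms$masks[[i]] & atoms$masks[[j]],
       node = new_bool("AND", list(atoms$queries[[i]]$root, atoms$queries[[j]]$root)),
       nleaves = atoms$nleaves[[i]] + atoms$nleaves[[j]])
}

clause_not <- function(i, j, atoms) {
  list(key = sprintf("n%03d-%03d", i, j),
       mask = atoms$masks[[i]] & !atoms$masks[[j]],
       node = new_bool("NOT", list(atoms$queries[[i]]$root, atoms$queries[[j]]$root)),
       nleaves = atoms$nleaves[[i]] + atoms$nleaves[[j]])
}

state_from_clauses <- function(clauses, labels) {
  keys <- vapply(clauses, `[[`, character(1), "key")
  ord <- order(keys, method = "radix")
  clauses <- clauses[ord]
  mask <- Reduce(`|`, lapply(clauses, `[[`, "mask"))
  n_rel <- sum(labels)
  sens <- if (n_rel > 0) sum(mask & labels) / n_rel else NA_real_
  spec <- if (n_rel < length(labels)) sum(!mask & !labels) / (length(labels) - n_rel) else NA_real_
  list(
    clauses = clauses,
    key = paste(vapply(clauses, `[[`, character(1), "key"), collapse = "|"),
    mask = mask, sens = sens, spec = spec,
    nleaves = sum(vapply(clauses, `[[`, integer(1), "nleaves"))
  )
}

objective_score <- function(state, config) {
  se <- if (is.na(state$sens)) 0 else state$sens
  sp <- if (is.na(state$spec)) 0 else state$spec
  switch(config$objective,
    balanced_youden = list(feasible = TRUE, value = se + sp - 1),
    max_sens_given_spec = list(feasible = sp >= config$spec_floor, value = se),
    max_spec_given_sens = list(feasible = se >= config$sens_floor, value = sp)
  )
}

state_rank_key <- function(state, config) {
  sc <- objective_score(state, config)
  # larger is better in the first two components
  c(feasible = as.numeric(sc$feasible), value = sc$value, nleaves = -state$nleaves)
}

rank_states <- function(states, config) {
  if (length(states) == 0L) return(states)
  keymat <- t(vapply(states, state_rank_key, numeric(3), config = config))
  keys <- vapply(states, `[[`, character(1), "key")
  states[order(-keymat[, 1L], -keymat[, 2L], -keymat[, 3L], keys, method = "radix")]
}

state_to_candidate <- function(state, dialect, labels, ci_method = "wald", level = 0.95) {
  nodes <- lapply(state$clauses, `[[`, "node")
  root <- if (length(nodes) == 1L) nodes[[1L]] else new_bool("OR", nodes)
  mask_candidate(new_query(root, dialect), state$mask, labels, ci_method, level)
}

#' Develop a multi-term filter by beam search
#'
#' Screens single-term candidates, then grows a filter of the form
#' OR(clause, ...) where each clause is a single atom or (when enabled) a
#' two-way conjunction or exclusion. Each step proposes adding one OR
#' clause (sensitivity direction) and refining an existing clause
#' (specificity direction), keeps the `beam_width` best states under the
#' objective, and stops when the best improvement falls below `epsilon` or
#' `max_or_clauses` is reached. The search is deterministic for a given
#' corpus, term pool, and configuration. Per-step monotonicity is asserted:
#' adding an OR clause never lowers sensitivity or raises specificity, and
#' refining a clause never raises sensitivity or lowers specificity.
#'
#' @param corpus A fully labeled development [labeled_corpus()].
#' @param thesaurus A [thesaurus()] or `NULL`.
#' @param terms List of [candidate_term()] objects, or a list of
#'   pre-enumerated single-term `fc_query` objects.
#' @param config A [develop_config()].
#' @param dialect Dialect for enumeration when `terms` are
#'   [candidate_term()] objects.
#' @return List of `filter_candidate` objects (the final beam, best
#'   first), with attribute `infeasible = TRUE` when no state satisfied
#'   the objective's floor (best-effort frontier).
#' @export
develop_filter <- function(corpus, thesaurus = NULL, terms, config = develop_config(),
                           dialect = c("pubmed", "ovid_medline", "ovid_embase")) {
  dialect <- match.arg(dialect)
  queries <- if (length(terms) && inherits(terms[[1L]], "fc_query")) {
    terms
  } else {
    enumerate_variants(terms, dialect, thesaurus)
  }
  if (length(queries)) dialect <- queries[[1L]]$dialect
  screened <- screen(queries, corpus, thesaurus, config)
  if (length(screened) == 0L) {
    stop("no candidate survived screening; relax screen_min_sens/screen_min_spec",
         call. = FALSE)
  }
  labels <- corpus_labels(corpus)
  index <- corpus_index(corpus)
  atoms <- list(
    queries = lapply(screened, `[[`, "query"),
    masks = lapply(screened, function(cd) {
      retrieve_mask(cd$query, corpus, index, thesaurus)
    }),
    nleaves = lapply(screened, function(cd) count_leaves(cd$query))
  )
  n_atoms <- length(atoms$queries)

  singles <- lapply(seq_len(n_atoms), function(i) {
    state_from_clauses(list(clause_atom(i, atoms)), labels)
  })
  beam <- rank_states(singles, config)[1L]
  best_score <- objective_score(beam[[1L]], config)

  repeat {
    proposals <- list()
    seen <- new.env(parent = emptyenv())
    propose <- function(state) {
      if (is.null(seen[[state$key]])) {
        seen[[state$key]] <- TRUE
        proposals[[length(proposals) + 1L]] <<- state
      }
    }
    for (state in beam) {
      clause_keys <- vapply(state$clauses, `[[`, character(1), "key")
      atom_in_state <- function(i) sprintf("a%03d", i) %in% clause_keys
      if (length(state$clauses) < config$max_or_clauses) {
        for (i in seq_len(n_atoms)) {
          if (atom_in_state(i)) next
          new_state <- state_from_clauses(c(state$clauses, list(clause_atom(i, atoms))),
                                          labels)
          stopifnot(is.na(state$sens) || new_state$sens >= state$sens,
                    is.na(state$spec) || new_state$spec <= state$spec)
          propose(new_state)
        }
      }
      for (ci in seq_along(state$clauses)) {
        cl <- state$clauses[[ci]]
        if (!startsWith(cl$key, "a")) next
        i <- as.integer(sub("^a", "", cl$key))
        others <- setdiff(seq_len(n_atoms), i)
        for (j in others) {
          refined <- list()
          if (config$allow_and_refinement) refined <- c(refined, list(clause_and(i, j, atoms)))
          if (config$allow_not) refined <- c(refined, list(clause_not(i, j, atoms)))
          for (rcl in refined) {
            new_clauses <- state$clauses
            new_clauses[[ci]] <- rcl
            new_state <- state_from_clauses(new_clauses, labels)
            stopifnot(is.na(state$sens) || new_state$sens <= state$sens,
                      is.na(state$spec) || new_state$spec >= state$spec)
            propose(new_state)
          }
        }
      }
    }
    if (length(proposals) == 0L) break
    pool <- rank_states(c(beam, proposals), config)
    new_best <- objective_score(pool[[1L]], config)
    improved <- (new_best$feasible && !best_score$feasible) ||
      (new_best$feasible == best_score$feasible &&
         new_best$value - best_score$value >= config$epsilon)
    if (!improved) break
    beam <- pool[seq_len(min(config$beam_width, length(pool)))]
    best_score <- new_best
  }

  out <- lapply(beam, state_to_candidate, dialect = dialect, labels = labels)
  if (!objective_score(beam[[1L]], config)$feasible) attr(out, "infeasible") <- TRUE
  out
}

#' Pareto frontier of evaluated filters
#'
#' Keeps the candidates not dominated in (sensitivity, specificity): a
#' candidate is dominated when another is at least as good on both metrics
#' and strictly better on one. Sorted by descending sensitivity; ties by
#' precision, then atom count.
#'
#' @param candidates List of `filter_candidate` objects evaluated on the
#'   same corpus.
#' @return Sublist forming the frontier.
#' @export
pareto_frontier <- function(candidates) {
  if (length(candidates) == 0L) return(candidates)
  se <- vapply(candidates, function(cd) cd$performance$sensitivity$estimate, numeric(1))
  sp <- vapply(candidates, function(cd) cd$performance$specificity$estimate, numeric(1))
  dominated <- vapply(seq_along(candidates), function(i) {
    any(se >= se[i] & sp >= sp[i] & (se > se[i] | sp > sp[i]))
  }, logical(1))
  keep <- candidates[!dominated]
  pr <- vapply(keep, function(cd) {
    p <- cd$performance$precision$estimate
    if (is.na(p)) -Inf else p
  }, numeric(1))
  nl <- vapply(keep, function(cd) count_leaves(cd$query), integer(1))
  keep[order(-vapply(keep, function(cd) cd$performance$sensitivity$estimate, numeric(1)),
             -pr, nl, method = "radix")]
}
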