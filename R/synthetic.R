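# Synthetic labeled citation corpora with known class-conditional
# structure, plus closed-form expected performance for planted queries.
#
# The generative model: each record gets a journal (round-robin), a
# Bernoulli(prevalence) relevance label, and, independently for every term
# profile, (i) a text occurrence drawn from the class-conditional
# probability — one surface form chosen by weight and inserted into the
# title or abstract — and (ii) an indexing event for the profile's
# descriptor, thinned by the indexing-dropout rate, with a major-topic flag.
# Filler tokens are drawn from a vocabulary disjoint from all profile
# surfaces, so the planted signal is unambiguous. Class-conditional
# independence across profiles is what makes expected performance a
# closed-form product; dependence between terms in real indexing is
# deliberately not modelled.

#' Define a planted term profile
#'
#' @param surfaces Character vector of surface forms (e.g. British and
#'   American spellings); one is chosen per occurrence.
#' @param weights Selection weights for the surfaces (default uniform).
#' @param p_text_rel,p_text_irr Probability the term appears in the
#'   title/abstract given the record is relevant / irrelevant.
#' @param descriptor Optional descriptor name for indexing events.
#' @param p_index_rel,p_index_irr Probability the record is indexed with
#'   `descriptor` given class (before dropout).
#' @param p_major_given_indexed Probability an indexing event carries the
#'   major-topic flag.
#' @return Object of class `term_profile`.
#' @export
term_profile <- function(surfaces, weights = NULL, p_text_rel = 0, p_text_irr = 0,
                         descriptor = NULL, p_index_rel = 0, p_index_irr = 0,
                         p_major_given_indexed = 0.5) {
  probs <- c(p_text_rel, p_text_irr, p_index_rel, p_index_irr, p_major_given_indexed)
  stopifnot(all(probs >= 0), all(probs <= 1))
  if ((p_text_rel > 0 || p_text_irr > 0) && length(surfaces) == 0L) {
    stop("a profile with text occurrence probability needs surfaces", call. = FALSE)
  }
  weights <- weights %||% rep(1, length(surfaces))
  stopifnot(length(weights) == length(surfaces), all(weights > 0))
  structure(
    list(surfaces = as.character(surfaces), weights = weights / sum(weights),
         p_text_rel = p_text_rel, p_text_irr = p_text_irr,
         descriptor = descriptor, p_index_rel = p_index_rel,
         p_index_irr = p_index_irr,
         p_major_given_indexed = p_major_given_indexed),
    class = "term_profile"
  )
}

#' Default planted profiles
#'
#' Three profiles of decreasing prevalence in the relevant class, one with
#' an indexed descriptor and one with a spelling variant pair; used as the
#' package's reference study condition.
#'
#' @return List of [term_profile()] objects.
#' @export
default_term_profiles <- function() {
  list(
    term_profile("proteinuria", p_text_rel = 0.90, p_text_irr = 0.05),
    term_profile("glomerulonephritis", p_text_rel = 0.60, p_text_irr = 0.02,
                 descriptor = "Glomerulonephritis",
                 p_index_rel = 0.60, p_index_irr = 0.03,
                 p_major_given_indexed = 0.5),
    term_profile(c("polyangiitis", "polyangitis"), weights = c(0.7, 0.3),
                 p_text_rel = 0.40, p_text_irr = 0.01)
  )
}

#' Configuration for the synthetic-corpus generator
#'
#' Defaults define the package's reference study condition: 20 journals of
#' 250 articles (5,000 records), 5% prevalence of relevant articles, the
#' [default_term_profiles()], and 10% indexing dropout.
#'
#' @param n_journals Number of journals (>= 2).
#' @param articles_per_journal Articles per journal.
#' @param prevalence Proportion of relevant articles in \[0, 1\].
#' @param profiles List of [term_profile()] objects.
#' @param filler_vocab_size Size of the filler-token vocabulary.
#' @param filler_terms_per_record Filler tokens per abstract (titles get
#'   three).
#' @param indexing_dropout Probability an indexing event is omitted.
#' @param journal_prevalence_multiplier Optional per-journal multiplier on
#'   `prevalence` (length `n_journals`), to emulate journals richer or
#'   poorer in relevant content; `NULL` disables journal effects.
#' @param seed Integer seed; a fixed seed makes the corpus byte-identical
#'   across runs.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_journals = 20L, articles_per_journal = 250L,
                             prevalence = 0.05, profiles = default_term_profiles(),
                             filler_vocab_size = 200L, filler_terms_per_record = 8L,
                             indexing_dropout = 0.10,
                             journal_prevalence_multiplier = NULL, seed = 1L) {
  stopifnot(n_journals >= 2L, articles_per_journal >= 1L,
            prevalence >= 0, prevalence <= 1,
            indexing_dropout >= 0, indexing_dropout <= 1,
            filler_vocab_size >= 1L, filler_terms_per_record >= 0L)
  if (!is.null(journal_prevalence_multiplier)) {
    stopifnot(length(journal_prevalence_multiplier) == n_journals,
              all(journal_prevalence_multiplier >= 0))
  }
  structure(
    list(n_journals = as.integer(n_journals),
         articles_per_journal = as.integer(articles_per_journal),
         prevalence = prevalence, profiles = profiles,
         filler_vocab_size = as.integer(filler_vocab_size),
         filler_terms_per_record = as.integer(filler_terms_per_record),
         indexing_dropout = indexing_dropout,
         journal_prevalence_multiplier = journal_prevalence_multiplier,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Read a generator configuration from YAML
#'
#' Top-level keys mirror the [generator_config()] arguments; `profiles` is
#' a list of mappings mirroring [term_profile()].
#'
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  profiles <- lapply(obj$profiles %||% list(), function(p) {
    term_profile(
      surfaces = unlist(p$surfaces), weights = unlist(p$weights),
      p_text_rel = p$p_text_rel %||% 0, p_text_irr = p$p_text_irr %||% 0,
      descriptor = p$descriptor,
      p_index_rel = p$p_index_rel %||% 0, p_index_irr = p$p_index_irr %||% 0,
      p_major_given_indexed = p$p_major_given_indexed %||% 0.5
    )
  })
  args <- obj[setdiff(names(obj), "profiles")]
  if (length(profiles)) args$profiles <- profiles
  do.call(generator_config, args)
}

filler_vocab <- function(config) sprintf("zq%04d", seq_len(config$filler_vocab_size))

insert_tokens <- function(tokens, phrase_tokens) {
  pos <- sample.int(length(tokens) + 1L, 1L) - 1L
  append(tokens, phrase_tokens, after = pos)
}

#' Generate a synthetic labeled corpus
#'
#' @param config A [generator_config()].
#' @param thesaurus A [thesaurus()] resolving every profile descriptor
#'   (error if one is unresolvable); may be `NULL` when no profile has a
#'   descriptor.
#' @return A fully labeled [labeled_corpus()]; deterministic given
#'   `config$seed`.
#' @export
generate <- function(config, thesaurus = NULL) {
  stopifnot(inherits(config, "generator_config"))
  for (p in config$profiles) {
    if (!is.null(p$descriptor)) {
      if (is.null(thesaurus)) {
        stop("profile descriptor '", p$descriptor, "' requires a thesaurus",
             call. = FALSE)
      }
      resolve_descriptor(thesaurus, p$descriptor)
    }
  }
  vocab <- filler_vocab(config)
  n <- config$n_journals * config$articles_per_journal
  mult <- config$journal_prevalence_multiplier %||% rep(1, config$n_journals)
  with_fixed_seed(config$seed, {
    records <- vector("list", n)
    labels <- logical(n)
    for (i in seq_len(n)) {
      j <- ((i - 1L) %% config$n_journals) + 1L
      prev_i <- min(1, config$prevalence * mult[j])
      relevant <- stats::runif(1) < prev_i
      title_toks <- sample(vocab, 3L, replace = TRUE)
      abstract_toks <- sample(vocab, config$filler_terms_per_record, replace = TRUE)
      index_terms <- list()
      for (p in config$profiles) {
        p_text <- if (relevant) p$p_text_rel else p$p_text_irr
        if (p_text > 0 && stats::runif(1) < p_text) {
          surface <- p$surfaces[sample.int(length(p$surfaces), 1L, prob = p$weights)]
          toks <- tokenize_text(surface)
          if (stats::runif(1) < 0.5) {
            title_toks <- insert_tokens(title_toks, toks)
          } else {
            abstract_toks <- insert_tokens(abstract_toks, toks)
          }
        }
        if (!is.null(p$descriptor)) {
          p_index <- if (relevant) p$p_index_rel else p$p_index_irr
          if (p_index > 0 && stats::runif(1) < p_index &&
              stats::runif(1) >= config$indexing_dropout) {
            index_terms[[length(index_terms) + 1L]] <- index_term(
              p$descriptor, major = stats::runif(1) < p$p_major_given_indexed
            )
          }
        }
      }
      records[[i]] <- citation_record(
        uid = sprintf("syn%06d", i),
        journal_id = sprintf("J%03d", j),
        pub_year = sample(2004:2008, 1L),
        title = paste(title_toks, collapse = " "),
        abstract = paste(abstract_toks, collapse = " "),
        index_terms = index_terms
      )
      labels[i] <- relevant
    }
    names(labels) <- vapply(records, `[[`, character(1), "uid")
    labeled_corpus(records, labels)
  })
}

# ---- closed-form expected performance ---------------------------------------

# probability that a text leaf matches, per class, via the share of profile
# surfaces it covers
leaf_profile_probs <- function(leaf, config, thesaurus) {
  probs_rel <- numeric()
  probs_irr <- numeric()
  if (leaf$kind == "text") {
    if (!(leaf$field %in% c("tw", "mp", "tiab"))) {
      stop("expected_performance covers fields tw/mp/tiab only (got '",
           leaf$field, "')", call. = FALSE)
    }
    compiled <- compile_phrase(leaf$surface)
    wide <- leaf$field %in% c("tw", "mp")
    keep <- 1 - config$indexing_dropout
    for (p in config$profiles) {
      share <- if (length(p$surfaces)) {
        sum(p$weights[vapply(p$surfaces, function(s) {
          length(phrase_starts(tokenize_text(s), compiled)) > 0L
        }, logical(1))])
      } else 0
      # the wide text-word scope also searches index-term descriptor
      # names, so an indexing event whose descriptor name contains the
      # phrase is a second, independent way for the leaf to match
      idx_hit <- wide && !is.null(p$descriptor) &&
        length(phrase_starts(tokenize_text(p$descriptor), compiled)) > 0L
      p_rel_i <- 1 - (1 - p$p_text_rel * share) *
        (1 - if (idx_hit) p$p_index_rel * keep else 0)
      p_irr_i <- 1 - (1 - p$p_text_irr * share) *
        (1 - if (idx_hit) p$p_index_irr * keep else 0)
      if (p_rel_i > 0 || p_irr_i > 0) {
        probs_rel <- c(probs_rel, p_rel_i)
        probs_irr <- c(probs_irr, p_irr_i)
      }
    }
  } else {
    name_set <- if (!is.null(thesaurus)) {
      canonical <- resolve_descriptor(thesaurus, leaf$surface)
      tolower(if (leaf$explode) descendants(thesaurus, canonical) else canonical)
    } else {
      tolower(leaf$surface)
    }
    keep <- 1 - config$indexing_dropout
    for (p in config$profiles) {
      if (is.null(p$descriptor)) next
      if (!(tolower(p$descriptor) %in% name_set)) next
      maj <- if (leaf$major) p$p_major_given_indexed else 1
      probs_rel <- c(probs_rel, p$p_index_rel * keep * maj)
      probs_irr <- c(probs_irr, p$p_index_irr * keep * maj)
    }
  }
  if (length(probs_rel) == 0L) {
    stop("query leaf '", leaf$surface, "' does not map to any generator profile",
         call. = FALSE)
  }
  c(rel = 1 - prod(1 - probs_rel), irr = 1 - prod(1 - probs_irr))
}

expected_node_prob <- function(node, config, thesaurus) {
  if (inherits(node, "fc_leaf")) {
    return(leaf_profile_probs(node, config, thesaurus))
  }
  if (inherits(node, "fc_prox")) {
    stop("expected_performance does not support adjacency nodes", call. = FALSE)
  }
  child_p <- lapply(node$children, expected_node_prob, config = config,
                    thesaurus = thesaurus)
  rel <- vapply(child_p, `[[`, numeric(1), "rel")
  irr <- vapply(child_p, `[[`, numeric(1), "irr")
  switch(node$op,
    OR = c(rel = 1 - prod(1 - rel), irr = 1 - prod(1 - irr)),
    AND = c(rel = prod(rel), irr = prod(irr)),
    NOT = c(rel = rel[1L] * (1 - rel[2L]), irr = irr[1L] * (1 - irr[2L]))
  )
}

#' Closed-form expected performance of a query under the generative model
#'
#' Computes the class-conditional match probability of an AND/OR/NOT query
#' over planted profile events by inclusion–exclusion, assuming
#' class-conditional independence across profiles (the generator's model):
#' P(OR) = 1 - prod(1 - p_i), P(AND) = prod(p_i),
#' P(A NOT B) = p_A (1 - p_B). Returns sensitivity = P(match | relevant)
#' and specificity = 1 - P(match | irrelevant). Every leaf must map to at
#' least one profile; adjacency nodes and fields outside tw/mp/tiab are
#' unsupported.
#'
#' @param query An `fc_query`.
#' @param config A [generator_config()].
#' @param thesaurus Optional [thesaurus()] used to resolve descriptor
#'   leaves (with explosion); without one, descriptor names are matched
#'   literally.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @examples
#' cfg <- generator_config()
#' expected_performance(parse_pubmed("proteinuria[tw]"), cfg)
#' @export
expected_performance <- function(query, config, thesaurus = NULL) {
  stopifnot(inherits(query, "fc_query"), inherits(config, "generator_config"))
  p <- expected_node_prob(query$root, config, thesaurus)
  c(sensitivity = unname(p["rel"]), specificity = unname(1 - p["irr"]))
}
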