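# Shared fixtures built in code: small thesauri, random corpora, and random
# queries for property-style tests.

fixture_mesh <- function() toy_mesh()

tiny_thesaurus <- function() {
  thesaurus(list(
    list(name = "Kidney Diseases", tree_numbers = "C12.419",
         entry_terms = "Kidney Disease"),
    list(name = "Glomerulonephritis", tree_numbers = "C12.419.570",
         entry_terms = "Bright Disease"),
    list(name = "IgA Nephropathy", tree_numbers = "C12.419.570.428"),
    list(name = "Membranous Glomerulonephritis", tree_numbers = "C12.419.570.570"),
    list(name = "Proteinuria", tree_numbers = "C12.934.734")
  ), vocabulary_id = "tiny")
}

# a random dot-coded tree of about n nodes, for explosion property tests
random_tree_thesaurus <- function(n, seed) {
  set.seed(seed)
  codes <- c("T1")
  while (length(codes) < n) {
    parent <- sample(codes, 1L)
    child <- paste0(parent, ".", sample(1:99, 1L))
    if (!(child %in% codes)) codes <- c(codes, child)
  }
  # occasionally give a descriptor a second tree number in another subtree
  descs <- lapply(seq_along(codes), function(i) {
    tns <- codes[i]
    list(name = paste0("D", i), tree_numbers = tns, entry_terms = character())
  })
  extra <- sample(seq_along(codes), max(1L, n %/% 10))
  for (i in extra) {
    tn2 <- paste0("T2.", i)
    descs[[i]]$tree_numbers <- c(descs[[i]]$tree_numbers, tn2)
  }
  thesaurus(descs, vocabulary_id = paste0("random", seed))
}

corpus_vocab <- c(
  "kidney", "renal", "disease", "biopsy", "lupus", "vasculitis", "purpura",
  "proteinuria", "glomerulonephritis", "polyangiitis", "polyangitis",
  "minimal", "change", "diabetic", "nephropathy", "chronic", "outcome",
  "therapy", "anti", "glomerular", "amyloid", "myeloma", "overt", "series"
)

fixture_descriptor_names <- c(
  "Kidney Diseases", "Glomerulonephritis", "Glomerulonephritis, IGA",
  "Proteinuria", "Vasculitis", "Lupus Erythematosus, Systemic",
  "Diabetes Mellitus, Type 2"
)

random_record <- function(uid, journal) {
  n_ti <- sample(4:9, 1L)
  n_ab <- sample(6:16, 1L)
  n_ix <- sample(0:3, 1L)
  index_terms <- lapply(sample(fixture_descriptor_names, n_ix), function(d) {
    index_term(d, major = runif(1) < 0.4,
               subheadings = if (runif(1) < 0.3) "therapy" else character())
  })
  citation_record(
    uid = uid, journal_id = journal, pub_year = sample(2004:2008, 1L),
    title = paste(sample(corpus_vocab, n_ti, replace = TRUE), collapse = " "),
    abstract = paste(sample(corpus_vocab, n_ab, replace = TRUE), collapse = " "),
    index_terms = index_terms,
    entry_term_strings = if (runif(1) < 0.2) "minimal change disease" else character(),
    classification_codes = if (runif(1) < 0.3) "Urology and Nephrology" else character()
  )
}

random_corpus <- function(n = 200L, seed = 1L, n_journals = 6L) {
  set.seed(seed)
  records <- lapply(seq_len(n), function(i) {
    random_record(sprintf("r%04d", i), sprintf("J%02d", ((i - 1L) %% n_journals) + 1L))
  })
  labels <- stats::setNames(runif(n) < 0.3,
                            vapply(records, `[[`, character(1), "uid"))
  labeled_corpus(records, labels)
}

# ---- random queries ---------------------------------------------------------

random_text_surface <- function(dialect) {
  n_words <- sample(1:2, 1L, prob = c(0.8, 0.2))
  words <- sample(corpus_vocab, n_words)
  r <- runif(1)
  if (r < 0.25) {
    # truncate the final word at a 4-6 character stem
    last <- words[n_words]
    stem <- substr(last, 1L, min(nchar(last), sample(4:6, 1L)))
    words[n_words] <- paste0(stem, if (dialect == "pubmed") "*" else "$")
  } else if (r < 0.35 && dialect != "pubmed") {
    # drop one interior character into a ?-wildcard
    last <- words[n_words]
    if (nchar(last) >= 4L) {
      k <- sample(2:(nchar(last) - 1L), 1L)
      words[n_words] <- paste0(substr(last, 1L, k - 1L), "?",
                               substr(last, k + 1L, nchar(last)))
    }
  }
  paste(words, collapse = " ")
}

random_leaf <- function(dialect) {
  if (runif(1) < 0.25) {
    name <- sample(fixture_descriptor_names, 1L)
    filtercraft:::new_descriptor_leaf(name, explode = runif(1) < 0.5,
                                      major = runif(1) < 0.3)
  } else {
    fields <- if (dialect == "pubmed") c("tw", "tiab", "ti") else c("mp", "tiab", "ti")
    filtercraft:::new_text_leaf(random_text_surface(dialect), sample(fields, 1L))
  }
}

random_prox <- function(dialect) {
  side <- function() {
    k <- sample(1:2, 1L)
    lapply(seq_len(k), function(i) {
      filtercraft:::new_text_leaf(sample(corpus_vocab, 1L), NA_character_)
    })
  }
  distance <- sample(1:3, 1L)
  filtercraft:::new_prox(side(), side(), distance = distance,
                         ordered = distance == 1L,
                         field = sample(c("mp", "tiab", "ti"), 1L))
}

random_node <- function(dialect, depth = 2L) {
  r <- runif(1)
  if (depth == 0L || r < 0.45) {
    if (dialect != "pubmed" && runif(1) < 0.15) return(random_prox(dialect))
    return(random_leaf(dialect))
  }
  op <- sample(c("AND", "OR", "OR", "NOT"), 1L)
  k <- if (op == "NOT") 2L else sample(2:3, 1L)
  children <- lapply(seq_len(k), function(i) random_node(dialect, depth - 1L))
  filtercraft:::new_bool(op, children)
}

random_query <- function(dialect = c("pubmed", "ovid_medline")) {
  dialect <- if (length(dialect) > 1L) sample(dialect, 1L) else dialect
  filtercraft:::new_query(random_node(dialect, depth = 2L), dialect)
}
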