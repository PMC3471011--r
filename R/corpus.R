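# Data model and I/O for labeled citation corpora.

#' Create an index term
#'
#' An index term is a controlled-vocabulary descriptor attached to a
#' citation by database indexing, optionally flagged as the major topic of
#' the article and qualified by subheadings.
#'
#' @param descriptor Descriptor name (non-empty string).
#' @param major Logical; `TRUE` if the term is tagged as a major topic.
#' @param subheadings Character vector of subheading strings (no duplicates).
#' @return An object of class `index_term`.
#' @export
index_term <- function(descriptor, major = FALSE, subheadings = character()) {
  assert_scalar_chr(descriptor, "descriptor")
  if (!nzchar(descriptor)) stop("descriptor name must be non-empty", call. = FALSE)
  subheadings <- as.character(subheadings)
  if (anyDuplicated(subheadings)) {
    stop("duplicate subheadings on index term '", descriptor, "'", call. = FALSE)
  }
  structure(
    list(descriptor = descriptor, major = isTRUE(major), subheadings = subheadings),
    class = "index_term"
  )
}

#' Create a citation record
#'
#' One bibliographic record: title and abstract free text, index terms,
#' indexing-derived synonym strings, Embase-style classification codes, and
#' the databases the record appears in.
#'
#' @param uid Unique record identifier.
#' @param journal_id Journal identifier.
#' @param pub_year Publication year (integer, >= 1800).
#' @param title Title text (non-empty).
#' @param abstract Abstract text (may be empty).
#' @param index_terms List of [index_term()] objects.
#' @param entry_term_strings Character vector of synonym strings attached by
#'   indexing.
#' @param classification_codes Character vector of section-code strings.
#' @param source_databases Subset of `c("pubmed", "medline", "embase")`.
#' @return An object of class `citation_record`.
#' @export
citation_record <- function(uid, journal_id, pub_year, title, abstract = "",
                            index_terms = list(),
                            entry_term_strings = character(),
                            classification_codes = character(),
                            source_databases = c("pubmed", "medline", "embase")) {
  assert_scalar_chr(uid, "uid")
  assert_scalar_chr(journal_id, "journal_id")
  assert_scalar_chr(title, "title")
  if (!nzchar(trimws(title))) stop("title must be non-empty (uid ", uid, ")", call. = FALSE)
  pub_year <- as.integer(pub_year)
  if (is.na(pub_year) || pub_year < 1800L) {
    stop("pub_year must be an integer >= 1800 (uid ", uid, ")", call. = FALSE)
  }
  if (length(abstract) == 0L || is.na(abstract)) abstract <- ""
  bad <- setdiff(source_databases, c("pubmed", "medline", "embase"))
  if (length(bad)) stop("unknown source database: ", paste(bad, collapse = ", "), call. = FALSE)
  index_terms <- lapply(index_terms, function(it) {
    if (inherits(it, "index_term")) it else do.call(index_term, it)
  })
  structure(
    list(
      uid = uid, journal_id = journal_id, pub_year = pub_year,
      title = title, abstract = abstract, index_terms = index_terms,
      entry_term_strings = as.character(entry_term_strings),
      classification_codes = as.character(classification_codes),
      source_databases = as.character(source_databases)
    ),
    class = "citation_record"
  )
}

#' Create a labeled corpus
#'
#' A collection of citation records plus (optionally partial) consensus
#' relevance labels keyed by uid. Functions that score retrieval against the
#' reference standard require every record to be labeled.
#'
#' @param records List of [citation_record()] objects.
#' @param labels Named logical vector of consensus labels (names are uids),
#'   or `NULL` for an unlabeled corpus.
#' @return An object of class `labeled_corpus`.
#' @export
labeled_corpus <- function(records, labels = NULL) {
  uids <- vapply(records, function(r) r$uid, character(1))
  dup <- uids[duplicated(uids)]
  if (length(dup)) stop("duplicate uid ", dup[1L], call. = FALSE)
  names(records) <- uids
  if (!is.null(labels)) {
    if (is.null(names(labels)) || !is.logical(labels)) {
      stop("labels must be a named logical vector", call. = FALSE)
    }
    unknown <- setdiff(names(labels), uids)
    if (length(unknown)) {
      stop("label refers to unknown uid ", unknown[1L], call. = FALSE)
    }
    if (anyDuplicated(names(labels))) {
      stop("duplicate label for uid ", names(labels)[duplicated(names(labels))][1L],
           call. = FALSE)
    }
  }
  structure(list(records = records, labels = labels), class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  nlab <- length(x$labels)
  cat(sprintf(
    "<labeled_corpus> %d records, %d journals, %s\n",
    length(x$records), length(corpus_journals(x)),
    if (nlab == 0L) "unlabeled"
    else sprintf("%d labeled (%d relevant)", nlab, sum(x$labels))
  ))
  invisible(x)
}

#' Corpus accessors
#'
#' `corpus_uids()` returns record identifiers in corpus order;
#' `corpus_journals()` the sorted set of journal identifiers;
#' `corpus_labels()` the consensus labels (error if any record is
#' unlabeled and `require_complete` is `TRUE`).
#'
#' @param corpus A [labeled_corpus()].
#' @param require_complete Require every record to be labeled.
#' @return Character vector of uids / journals, or named logical labels.
#' @export
corpus_uids <- function(corpus) names(corpus$records)

#' @rdname corpus_uids
#' @export
corpus_journals <- function(corpus) {
  sort(unique(vapply(corpus$records, function(r) r$journal_id, character(1))))
}

#' @rdname corpus_uids
#' @export
corpus_labels <- function(corpus, require_complete = TRUE) {
  labs <- corpus$labels
  if (require_complete) {
    missing <- setdiff(corpus_uids(corpus), names(labs))
    if (length(missing)) {
      stop("corpus is not fully labeled; first unlabeled uid: ", missing[1L],
           call. = FALSE)
    }
  }
  labs[corpus_uids(corpus)[corpus_uids(corpus) %in% names(labs)]]
}

#' Subset a corpus
#'
#' `corpus_subset()` keeps the named uids; `corpus_view_journals()` keeps
#' records published in the given journals (e.g. one side of a
#' [split_by_journal()] split); `corpus_view_database()` keeps records
#' present in a given source database.
#'
#' @param corpus A [labeled_corpus()].
#' @param uids,journals Identifiers to keep.
#' @param database One of `"pubmed"`, `"medline"`, `"embase"`.
#' @return A [labeled_corpus()].
#' @export
corpus_subset <- function(corpus, uids) {
  unknown <- setdiff(uids, corpus_uids(corpus))
  if (length(unknown)) stop("unknown uid ", unknown[1L], call. = FALSE)
  records <- corpus$records[uids]
  labels <- corpus$labels[names(corpus$labels) %in% uids]
  labeled_corpus(records, if (length(labels)) labels else NULL)
}

#' @rdname corpus_subset
#' @export
corpus_view_journals <- function(corpus, journals) {
  keep <- vapply(corpus$records, function(r) r$journal_id %in% journals, logical(1))
  corpus_subset(corpus, corpus_uids(corpus)[keep])
}

#' @rdname corpus_subset
#' @export
corpus_view_database <- function(corpus, database) {
  database <- match.arg(database, c("pubmed", "medline", "embase"))
  keep <- vapply(corpus$records, function(r) database %in% r$source_databases, logical(1))
  corpus_subset(corpus, corpus_uids(corpus)[keep])
}

#' Derive consensus labels from per-reader labels
#'
#' Majority vote across readers per uid; an exact tie is an error (the
#' reference-standard protocol assumes calibrated readers and defines no
#' tie rule).
#'
#' @param reader_labels Data frame with columns `uid`, `relevant` (logical),
#'   `reader_id`.
#' @return Named logical vector of consensus labels.
#' @export
consensus_labels <- function(reader_labels) {
  stopifnot(is.data.frame(reader_labels),
            all(c("uid", "relevant", "reader_id") %in% names(reader_labels)))
  split_rel <- split(reader_labels$relevant, reader_labels$uid)
  out <- vapply(names(split_rel), function(u) {
    v <- split_rel[[u]]
    yes <- sum(v); no <- sum(!v)
    if (yes == no) stop("tied reader votes for uid ", u, call. = FALSE)
    yes > no
  }, logical(1))
  out
}

# ---- JSONL I/O --------------------------------------------------------------

record_to_list <- function(r, relevant = NULL) {
  out <- list(
    uid = r$uid, journal_id = r$journal_id, pub_year = r$pub_year,
    title = r$title, abstract = r$abstract,
    index_terms = lapply(r$index_terms, function(it) {
      list(descriptor = it$descriptor, major = it$major,
           subheadings = as.list(it$subheadings))
    }),
    entry_term_strings = as.list(r$entry_term_strings),
    classification_codes = as.list(r$classification_codes),
    source_databases = as.list(r$source_databases)
  )
  if (!is.null(relevant) && !is.na(relevant)) out$relevant <- relevant
  out
}

#' Load a labeled corpus from disk
#'
#' Two formats are supported. The JSONL citation dialect has one JSON object
#' per line with fields `uid`, `journal_id`, `pub_year`, `title`,
#' `abstract`, `index_terms` (`descriptor`/`major`/`subheadings`),
#' `entry_term_strings`, `classification_codes`, `source_databases`, and an
#' optional boolean `relevant`. The MEDLINE `.nbib` subset reads `PMID`
#' (uid), `TA` (journal), `DP` (year = first four digits), `TI`, `AB`, and
#' `MH` lines; on an `MH` line `/` separates subheadings and a leading `*`
#' on the descriptor or a subheading marks the term as major topic. Unknown
#' `.nbib` tags are skipped with one warning listing them. For `.nbib`
#' input, labels may be supplied by a sidecar file `<path>.labels` (TSV:
#' uid, relevant).
#'
#' @param path File path.
#' @param format `"jsonl"` or `"nbib"`.
#' @return A [labeled_corpus()]; record order follows the input.
#' @export
load_corpus <- function(path, format = c("jsonl", "nbib")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, jsonl = load_corpus_jsonl(path), nbib = load_corpus_nbib(path))
}

load_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  labels <- logical(0)
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop("malformed JSONL record at line ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    rec <- tryCatch(
      citation_record(
        uid = obj$uid, journal_id = obj$journal_id, pub_year = obj$pub_year,
        title = obj$title, abstract = obj$abstract %||% "",
        index_terms = lapply(obj$index_terms %||% list(), function(it) {
          index_term(it$descriptor, isTRUE(it$major),
                     unlist(it$subheadings, use.names = FALSE) %||% character())
        }),
        entry_term_strings = unlist(obj$entry_term_strings, use.names = FALSE) %||% character(),
        classification_codes = unlist(obj$classification_codes, use.names = FALSE) %||% character(),
        source_databases = unlist(obj$source_databases, use.names = FALSE) %||%
          c("pubmed", "medline", "embase")
      ),
      error = function(e) stop("malformed record at line ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    records[[i]] <- rec
    if (!is.null(obj$relevant)) {
      labels[rec$uid] <- isTRUE(obj$relevant)
    }
  }
  uids <- vapply(records, function(r) r$uid, character(1))
  dup <- uids[duplicated(uids)]
  if (length(dup)) stop("duplicate uid ", dup[1L], call. = FALSE)
  labeled_corpus(records, if (length(labels)) labels else NULL)
}

#' Write a corpus in the JSONL citation dialect
#'
#' Inverse of `load_corpus(..., format = "jsonl")`: `load_corpus()` on the
#' written file reproduces the corpus field by field.
#'
#' @param corpus A [labeled_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus$records, function(r) {
    rel <- if (r$uid %in% names(corpus$labels)) corpus$labels[[r$uid]] else NULL
    as.character(jsonlite::toJSON(record_to_list(r, rel), auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- .nbib subset -----------------------------------------------------------

parse_mh_field <- function(value) {
  parts <- strsplit(value, "/", fixed = TRUE)[[1L]]
  major <- any(startsWith(parts, "*"))
  parts <- sub("^\\*", "", parts)
  index_term(trimws(parts[1L]), major = major,
             subheadings = trimws(parts[-1L]))
}

load_corpus_nbib <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # fold continuation lines (indented) into the preceding tag line
  fields <- list()  # per record: list of c(tag, value)
  records <- list()
  unknown_tags <- character()
  cur <- list()
  cur_tag <- NULL
  flush_record <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    get1 <- function(tag) {
      v <- unlist(cur[names(cur) == tag], use.names = FALSE)
      if (length(v)) v[[1L]] else NA_character_
    }
    pmid <- get1("PMID")
    if (is.na(pmid)) stop("nbib record without PMID", call. = FALSE)
    year <- suppressWarnings(as.integer(substr(get1("DP"), 1L, 4L)))
    mh <- lapply(unlist(cur[names(cur) == "MH"], use.names = FALSE), parse_mh_field)
    ta <- get1("TA"); ab <- get1("AB")
    citation_record(
      uid = trimws(pmid), journal_id = if (is.na(ta)) "unknown" else trimws(ta),
      pub_year = year, title = get1("TI"), abstract = if (is.na(ab)) "" else ab,
      index_terms = mh,
      source_databases = c("pubmed", "medline")
    )
  }
  known <- c("PMID", "TA", "DP", "TI", "AB", "MH")
  i <- 0L
  for (line in lines) {
    i <- i + 1L
    if (!nzchar(trimws(line))) {
      rec <- tryCatch(flush_record(cur), error = function(e) {
        stop("malformed nbib record ending at line ", i, ": ",
             conditionMessage(e), call. = FALSE)
      })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
      cur <- list(); cur_tag <- NULL
      next
    }
    if (grepl("^\\s+", line)) {
      if (!is.null(cur_tag) && length(cur)) {
        cur[[length(cur)]] <- paste(cur[[length(cur)]], trimws(line))
      }
      next
    }
    m <- regmatches(line, regexec("^([A-Z0-9]{1,4})\\s*-\\s?(.*)$", line))[[1L]]
    if (length(m) == 0L) {
      stop("malformed nbib line ", i, ": ", line, call. = FALSE)
    }
    tag <- m[2L]; value <- m[3L]
    if (!(tag %in% known)) {
      unknown_tags <- union(unknown_tags, tag)
      cur_tag <- NULL
      next
    }
    cur[[length(cur) + 1L]] <- value
    names(cur)[length(cur)] <- tag
    cur_tag <- tag
  }
  rec <- tryCatch(flush_record(cur), error = function(e) {
    stop("malformed nbib record ending at line ", i, ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  if (length(unknown_tags)) {
    warning("ignored unknown nbib tags: ", paste(sort(unknown_tags), collapse = ", "),
            call. = FALSE)
  }
  uids <- vapply(records, function(r) r$uid, character(1))
  dup <- uids[duplicated(uids)]
  if (length(dup)) stop("duplicate uid ", dup[1L], call. = FALSE)
  labels <- NULL
  sidecar <- paste0(path, ".labels")
  if (file.exists(sidecar)) {
    tab <- utils::read.table(sidecar, sep = "\t", header = FALSE,
                             col.names = c("uid", "relevant"),
                             colClasses = c("character", "logical"))
    labels <- stats::setNames(tab$relevant, tab$uid)
  }
  labeled_corpus(records, labels)
}

# ---- journal split ----------------------------------------------------------

#' Split a corpus into development and validation journal sets
#'
#' Journals (not articles) are randomly permuted under `seed` and divided in
#' the requested ratio: the first `floor(n * r1 / (r1 + r2))` permuted
#' journals form the development set, the rest the validation set. The split
#' depends only on the journal set, ratio, and seed, so re-ordering records
#' never changes it. Splitting at the journal level mirrors how topic-filter
#' studies keep whole journals out of development, so validation estimates
#' generalize to unseen journals.
#'
#' @param corpus A [labeled_corpus()] with at least two distinct journals.
#' @param ratio Integer pair, e.g. `c(2, 1)` for a two-to-one split.
#' @param seed Integer seed (Mersenne-Twister permutation, see
#'   [with_fixed_seed()]).
#' @return An object of class `journal_split` with elements
#'   `development_journals`, `validation_journals`, `ratio`, `seed`.
#' @examples
#' \dontrun{
#' split <- split_by_journal(corpus, c(2, 1), seed = 7)
#' dev <- corpus_view_journals(corpus, split$development_journals)
#' }
#' @export
split_by_journal <- function(corpus, ratio = c(2, 1), seed) {
  if (length(ratio) != 2L || any(ratio <= 0) || any(ratio != as.integer(ratio))) {
    stop("ratio must be a pair of positive integers", call. = FALSE)
  }
  journals <- corpus_journals(corpus)
  if (length(journals) < 2L) stop("corpus must contain at least 2 journals", call. = FALSE)
  perm <- with_fixed_seed(seed, sample(journals))
  n_dev <- floor(length(journals) * ratio[1L] / sum(ratio))
  structure(
    list(
      development_journals = sort(perm[seq_len(n_dev)]),
      validation_journals = sort(perm[-seq_len(n_dev)]),
      ratio = as.integer(ratio), seed = as.integer(seed)
    ),
    class = "journal_split"
  )
}

#' @export
print.journal_split <- function(x, ...) {
  cat(sprintf("<journal_split> %d development / %d validation journals (ratio %d:%d, seed %d)\n",
              length(x$development_journals), length(x$validation_journals),
              x$ratio[1L], x$ratio[2L], x$seed))
  invisible(x)
}
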