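# Controlled-vocabulary trees (MeSH-like / Emtree-like) with dot-coded tree
# numbers, entry-term synonymy, and explosion.

norm_descriptor_name <- function(x) {
  x <- gsub('^"|"$', "", trimws(x))
  x <- tolower(gsub("[[:space:]]+", " ", x))
  x
}

# "lupus erythematosus, systemic" -> "systemic lupus erythematosus"
uninvert_name <- function(x) {
  parts <- strsplit(x, ",[[:space:]]*")[[1L]]
  if (length(parts) != 2L) return(NULL)
  paste(parts[2L], parts[1L])
}

#' Construct a thesaurus
#'
#' @param descriptors List of descriptor entries, each a list with `name`
#'   (canonical descriptor string), `tree_numbers` (character vector of
#'   dot-separated codes, at least one), and optional `entry_terms`
#'   (character vector of synonyms).
#' @param vocabulary_id Identifier for the vocabulary (e.g. `"toy-mesh"`).
#' @return An object of class `thesaurus`.
#' @export
thesaurus <- function(descriptors, vocabulary_id = "thesaurus") {
  by_name <- new.env(parent = emptyenv())
  by_entry <- new.env(parent = emptyenv())
  seen_tn <- new.env(parent = emptyenv())
  descriptors <- lapply(descriptors, function(d) {
    stopifnot(!is.null(d$name))
    tn <- as.character(d$tree_numbers %||% character())
    if (length(tn) == 0L) {
      stop("descriptor '", d$name, "' has no tree numbers", call. = FALSE)
    }
    for (t in tn) {
      if (!is.null(seen_tn[[t]])) {
        stop("duplicate tree number ", t, " (", seen_tn[[t]], " / ", d$name, ")",
             call. = FALSE)
      }
      seen_tn[[t]] <- d$name
    }
    d$entry_terms <- as.character(d$entry_terms %||% character())
    d$tree_numbers <- tn
    key <- norm_descriptor_name(d$name)
    if (!is.null(by_name[[key]])) {
      stop("duplicate descriptor name '", d$name, "'", call. = FALSE)
    }
    by_name[[key]] <- d$name
    for (e in d$entry_terms) by_entry[[norm_descriptor_name(e)]] <- d$name
    d
  })
  names(descriptors) <- vapply(descriptors, `[[`, character(1), "name")
  structure(
    list(descriptors = descriptors, vocabulary_id = vocabulary_id,
         by_name = by_name, by_entry = by_entry),
    class = "thesaurus"
  )
}

#' @export
print.thesaurus <- function(x, ...) {
  cat(sprintf("<thesaurus> '%s': %d descriptors\n",
              x$vocabulary_id, length(x$descriptors)))
  invisible(x)
}

#' Load a thesaurus file
#'
#' JSON format: `{"vocabulary_id": ..., "descriptors": [{"name": ...,
#' "tree_numbers": [...], "entry_terms": [...]}]}`. TSV format: three
#' tab-separated columns (name, semicolon-joined tree numbers,
#' semicolon-joined entry terms); the format is chosen by file extension.
#'
#' @param path Path to a `.json` or `.tsv` file.
#' @return A [thesaurus()].
#' @export
load_thesaurus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    descs <- lapply(obj$descriptors, function(d) {
      list(name = d$name,
           tree_numbers = unlist(d$tree_numbers, use.names = FALSE),
           entry_terms = unlist(d$entry_terms, use.names = FALSE) %||% character())
    })
    thesaurus(descs, obj$vocabulary_id %||% "thesaurus")
  } else if (ext %in% c("tsv", "txt")) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("name", "tree_numbers", "entry_terms"),
                             fill = TRUE)
    descs <- lapply(seq_len(nrow(tab)), function(i) {
      split_semi <- function(x) {
        if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, ";")[[1L]])
      }
      list(name = tab$name[i],
           tree_numbers = split_semi(tab$tree_numbers[i]),
           entry_terms = split_semi(tab$entry_terms[i]))
    })
    thesaurus(descs, tools::file_path_sans_ext(basename(path)))
  } else {
    stop("unsupported thesaurus format: .", ext, call. = FALSE)
  }
}

#' Resolve a name or entry term to its canonical descriptor
#'
#' Matching is case-insensitive, ignores surrounding quotes and repeated
#' whitespace, falls back to entry-term synonyms, and tries the comma
#' inversion (`"Lupus Erythematosus, Systemic"` also matches a descriptor
#' named `"Systemic Lupus Erythematosus"`, and vice versa).
#'
#' @param th A [thesaurus()].
#' @param name Descriptor name, entry term, or inverted form.
#' @return The canonical descriptor name, or `NULL` if unknown.
#' @export
lookup_descriptor <- function(th, name) {
  key <- norm_descriptor_name(name)
  hit <- th$by_name[[key]] %||% th$by_entry[[key]]
  if (!is.null(hit)) return(hit)
  un <- uninvert_name(key)
  if (!is.null(un)) {
    hit <- th$by_name[[un]] %||% th$by_entry[[un]]
    if (!is.null(hit)) return(hit)
  }
  NULL
}

resolve_descriptor <- function(th, name) {
  hit <- lookup_descriptor(th, name)
  if (is.null(hit)) {
    stop("unknown descriptor '", name, "' in vocabulary '", th$vocabulary_id, "'",
         call. = FALSE)
  }
  hit
}

#' Explode a descriptor to itself plus all descendants
#'
#' A descriptor D is a descendant of Q when any tree number of D extends any
#' tree number of Q by one or more dot-separated segments. Exploding a
#' search on a heading therefore also retrieves records indexed with any
#' narrower heading, e.g. exploding a glomerulonephritis heading pulls in
#' its specific histologic subtypes.
#'
#' @param th A [thesaurus()].
#' @param name Descriptor name or entry term (error if unknown).
#' @return Character vector of canonical descriptor names, sorted,
#'   including the descriptor itself.
#' @export
descendants <- function(th, name) {
  canonical <- resolve_descriptor(th, name)
  roots <- th$descriptors[[canonical]]$tree_numbers
  prefixes <- paste0(roots, ".")
  hits <- vapply(th$descriptors, function(d) {
    any(vapply(d$tree_numbers, function(tn) {
      any(startsWith(tn, prefixes))
    }, logical(1)))
  }, logical(1))
  sort(unique(c(canonical, names(th$descriptors)[hits])))
}
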