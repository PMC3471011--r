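# The six published glomerular-disease filters, shipped verbatim as
# executable fixtures under inst/extdata/filters/. Names follow the
# database_objective convention. The stored strings are the printed filter
# texts; the only normalizations are single spacing and ASCII quotes (the
# source table is typeset), and the Embase classification term
# `"Urology and nephrology".ec` keeps its printed capitalization.

PUBLISHED_FILTER_NAMES <- c(
  "pubmed_high_sensitivity", "pubmed_high_specificity",
  "medline_high_sensitivity", "medline_high_specificity",
  "embase_high_sensitivity", "embase_high_specificity"
)

#' Names of the shipped published filters
#'
#' @return Character vector of the six filter names.
#' @export
published_filter_names <- function() PUBLISHED_FILTER_NAMES

published_filter_path <- function(name) {
  if (!(name %in% PUBLISHED_FILTER_NAMES)) {
    stop("unknown filter '", name, "'; valid names: ",
         paste(PUBLISHED_FILTER_NAMES, collapse = ", "), call. = FALSE)
  }
  system.file("extdata", "filters", paste0(name, ".txt"),
              package = "filtercraft", mustWork = TRUE)
}

#' Verbatim source text of a published filter
#'
#' @param name One of [published_filter_names()].
#' @return The filter string.
#' @export
published_filter_text <- function(name) {
  lines <- readLines(published_filter_path(name), warn = FALSE, encoding = "UTF-8")
  paste(trimws(lines[!grepl("^#", lines)]), collapse = " ")
}

#' Load and parse a published filter
#'
#' @param name One of [published_filter_names()] (error listing the valid
#'   names otherwise).
#' @return An `fc_query`.
#' @examples
#' \dontrun{
#' q <- load_published_filter("pubmed_high_sensitivity")
#' count_leaves(q) # > 50 atoms
#' }
#' @export
load_published_filter <- function(name) {
  read_filter_file(published_filter_path(name))
}

#' Load the bundled toy vocabularies
#'
#' Small MeSH-like and Emtree-like trees covering every descriptor named in
#' the published filters; stand-ins for the licensed full vocabularies,
#' adequate for parsing, explosion, and evaluation on synthetic corpora.
#'
#' @return A [thesaurus()].
#' @export
toy_mesh <- function() {
  load_thesaurus(system.file("extdata", "thesauri", "toy_mesh.json",
                             package = "filtercraft", mustWork = TRUE))
}

#' @rdname toy_mesh
#' @export
toy_emtree <- function() {
  load_thesaurus(system.file("extdata", "thesauri", "toy_emtree.json",
                             package = "filtercraft", mustWork = TRUE))
}
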