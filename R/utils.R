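#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code under a fixed, portable random seed
#'
#' Evaluates `code` with the RNG set to Mersenne-Twister (inversion normals,
#' rejection sampling) seeded with `seed`, and restores the caller's RNG
#' state afterwards. All seeded operations in the package (journal splits,
#' corpus generation) go through this helper so results are portable across
#' platforms and R sessions.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_fixed_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (has_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  code
}

#' Round a proportion to one decimal place of percent
#'
#' Converts a proportion to percent and rounds half away from zero to one
#' decimal, the convention used in printed filter-performance tables.
#'
#' @param p Numeric vector of proportions in \[0, 1\] (NA allowed).
#' @return Numeric vector of percentages rounded to one decimal.
#' @examples
#' percent1(0.9015) # 90.2
#' @export
percent1 <- function(p) {
  pct <- p * 100
  sign(pct) * floor(abs(pct) * 10 + 0.5) / 10
}

#' @rdname percent1
#' @export
format_percent <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.1f", percent1(p)))
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single string", call. = FALSE)
  }
  invisible(x)
}
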