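# Contingency-table construction and diagnostic-accuracy statistics.
#
# Retrieval is scored like a diagnostic test against the reference-standard
# labels:
#
#                     relevant   non-relevant
#   retrieved             a           b
#   not retrieved         c           d
#
#   sensitivity = a/(a+c)   specificity = d/(b+d)
#   precision   = a/(a+b)   accuracy    = (a+d)/n

#' Build a 2x2 contingency table from a retrieved set
#'
#' @param retrieved Character vector of retrieved uids (subset of the
#'   corpus; unknown uids are an error).
#' @param corpus A fully labeled [labeled_corpus()].
#' @return Object of class `contingency_table` with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
contingency <- function(retrieved, corpus) {
  labels <- corpus_labels(corpus)
  unknown <- setdiff(retrieved, names(labels))
  if (length(unknown)) {
    stop("retrieved uid not in corpus: ", unknown[1L], call. = FALSE)
  }
  hit <- names(labels) %in% retrieved
  contingency_table(
    a = sum(hit & labels), b = sum(hit & !labels),
    c = sum(!hit & labels), d = sum(!hit & !labels)
  )
}

#' @rdname contingency
#' @param a,b,c,d Non-negative integer cell counts (at least one positive).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != as.integer(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("contingency table must contain at least one count", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("retrieved", "not retrieved"),
                              c("relevant", "non-relevant")))
  print(m)
  invisible(x)
}

ci_proportion <- function(x, n, method, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  if (method == "wald") {
    if (p %in% c(0, 1)) {
      # degenerate: the Wald interval collapses to the point estimate
      return(list(lower = p, upper = p, note = "degenerate Wald interval; consider Wilson"))
    }
    half <- z * sqrt(p * (1 - p) / n)
    list(lower = p - half, upper = p + half, note = NA_character_)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    list(lower = centre - half, upper = centre + half, note = NA_character_)
  }
}

#' Diagnostic performance of a contingency table
#'
#' Computes sensitivity, specificity, precision, and accuracy with
#' confidence intervals. A metric whose denominator is zero is undefined
#' and reported as `NA`, not 0. The default interval is the Wald normal
#' approximation (symmetric about the point estimate, matching how filter
#' studies usually print intervals); Wilson score intervals are available
#' and never leave \[0, 1\].
#'
#' @param table A [contingency_table()].
#' @param ci_method `"wald"` or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @return Object of class `diagnostic_performance`: a list of metrics,
#'   each with `estimate`, `lower`, `upper`, `x`, `n`.
#' @examples
#' performance(contingency_table(902, 130, 98, 870))
#' @export
performance <- function(table, ci_method = c("wald", "wilson"), level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  ci_method <- match.arg(ci_method)
  metric <- function(x, n) {
    if (n == 0L) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  x = x, n = n, note = "undefined: zero denominator"))
    }
    ci <- ci_proportion(x, n, ci_method, level)
    list(estimate = x / n, lower = ci$lower, upper = ci$upper, x = x, n = n,
         note = ci$note)
  }
  n <- table$a + table$b + table$c + table$d
  structure(
    list(
      sensitivity = metric(table$a, table$a + table$c),
      specificity = metric(table$d, table$b + table$d),
      precision = metric(table$a, table$a + table$b),
      accuracy = metric(table$a + table$d, n),
      table = table, ci_method = ci_method, level = level
    ),
    class = "diagnostic_performance"
  )
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  for (nm in c("sensitivity", "specificity", "precision", "accuracy")) {
    m <- x[[nm]]
    cat(sprintf("%-12s %s%% (%s-%s)\n", nm, format_percent(m$estimate),
                format_percent(m$lower), format_percent(m$upper)))
  }
  cat(sprintf("[%s %.0f%% CI; a=%d b=%d c=%d d=%d]\n", x$ci_method,
              100 * x$level, x$table$a, x$table$b, x$table$c, x$table$d))
  invisible(x)
}

#' @export
as.data.frame.diagnostic_performance <- function(x, ...) {
  rows <- lapply(c("sensitivity", "specificity", "precision", "accuracy"),
                 function(nm) {
    m <- x[[nm]]
    data.frame(metric = nm, estimate = m$estimate, lower = m$lower,
               upper = m$upper, x = m$x, n = m$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ci_method <- x$ci_method
  out$level <- x$level
  out
}

#' Youden index of a performance object
#'
#' Sensitivity + specificity - 1, the balanced discrimination measure used
#' to rank candidate filters.
#'
#' @param perf A [performance()] object.
#' @return Numeric scalar (`-Inf` when either metric is undefined).
#' @export
youden <- function(perf) {
  se <- perf$sensitivity$estimate
  sp <- perf$specificity$estimate
  if (is.na(se) || is.na(sp)) return(-Inf)
  se + sp - 1
}

#' Cohen's kappa for two raters, two categories
#'
#' Chance-corrected agreement between two paired boolean label vectors,
#' kappa = (p_o - p_e) / (1 - p_e) with marginal-product expected agreement.
#' When both raters assign the same single category throughout, p_e = 1 and
#' kappa is undefined (`NA` with a warning).
#'
#' @param labels_1,labels_2 Logical vectors of equal length >= 1.
#' @return Numeric kappa.
#' @examples
#' cohen_kappa(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 50)) # 1
#' @export
cohen_kappa <- function(labels_1, labels_2) {
  stopifnot(is.logical(labels_1), is.logical(labels_2),
            length(labels_1) == length(labels_2), length(labels_1) >= 1L)
  n <- length(labels_1)
  po <- mean(labels_1 == labels_2)
  p1 <- mean(labels_1)
  p2 <- mean(labels_2)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (pe >= 1) {
    warning("kappa undefined: expected agreement is 1 (both raters constant)",
            call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Prevalence implied by sensitivity, specificity, and precision
#'
#' Solves precision = se * p / (se * p + (1 - sp) * (1 - p)) for the
#' prevalence p, the unique value making the positive predictive value
#' equal `ppv` given `(se, sp)`:
#' p = ppv (1 - sp) / (se (1 - ppv) + ppv (1 - sp)).
#'
#' @param se,sp,ppv Proportions in \[0, 1\]; `se = 1, sp = 1` is an error
#'   (a perfect test's precision carries no prevalence information).
#' @return Prevalence in \[0, 1\].
#' @export
invert_to_prevalence <- function(se, sp, ppv) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1, ppv >= 0, ppv <= 1)
  if (se == 1 && sp == 1) {
    stop("prevalence is unidentified when se = 1 and sp = 1", call. = FALSE)
  }
  denom <- se * (1 - ppv) + ppv * (1 - sp)
  if (denom == 0) stop("prevalence is unidentified for these inputs", call. = FALSE)
  ppv * (1 - sp) / denom
}

#' Accuracy implied by sensitivity, specificity, and precision
#'
#' Accuracy = se * p + sp * (1 - p), with the prevalence p recovered by
#' [invert_to_prevalence()]. Useful as a consistency check on printed
#' performance rows: the four metrics of one 2x2 table are mutually
#' redundant, so accuracy can be recomputed from the other three.
#'
#' @inheritParams invert_to_prevalence
#' @return Accuracy as a proportion.
#' @examples
#' percent1(implied_accuracy(0.957, 0.986, 0.711)) # 98.5
#' @export
implied_accuracy <- function(se, sp, ppv) {
  p <- invert_to_prevalence(se, sp, ppv)
  se * p + sp * (1 - p)
}

#' Write a machine-readable performance report
#'
#' One row per evaluated filter: source text, the four cells, and the four
#' metrics with intervals — the machine version of a published performance
#' table row.
#'
#' @param candidates List of filter candidates (see [screen()]), or a
#'   single candidate.
#' @param path Output path; format chosen by extension (`.tsv` or `.json`).
#' @return The report data frame, invisibly.
#' @export
write_performance_report <- function(candidates, path) {
  if (inherits(candidates, "filter_candidate")) candidates <- list(candidates)
  df <- do.call(rbind, lapply(candidates, candidate_row))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}

candidate_row <- function(cand) {
  p <- cand$performance
  t <- cand$table
  row <- data.frame(
    filter = to_string(cand$query), a = t$a, b = t$b, c = t$c, d = t$d,
    stringsAsFactors = FALSE
  )
  for (nm in c("sensitivity", "specificity", "precision", "accuracy")) {
    row[[nm]] <- percent1(p[[nm]]$estimate)
    row[[paste0(nm, "_lo")]] <- percent1(p[[nm]]$lower)
    row[[paste0(nm, "_hi")]] <- percent1(p[[nm]]$upper)
  }
  row$ci_method <- p$ci_method
  row$level <- p$level
  row
}
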