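# helper: corpus where given uids contain given title words
term_corpus <- function(spec_rows) {
  # spec_rows: list of list(uid, words, relevant)
  recs <- lapply(spec_rows, function(r) {
    citation_record(r$uid, r$journal %||% "J1", 2005,
                    title = paste(c("filler", r$words), collapse = " "))
  })
  labels <- stats::setNames(vapply(spec_rows, function(r) r$relevant, logical(1)),
                            vapply(spec_rows, function(r) r$uid, character(1)))
  labeled_corpus(recs, labels)
}

test_that("variant enumeration covers the field/truncation/descriptor grid", {
  expect_identical(enumerate_variants(list(), "pubmed"), list())

  tq <- enumerate_variants(
    list(candidate_term("nephropathy", fields = c("tw", "tiab", "ti"), truncation = TRUE)),
    "pubmed"
  )
  expect_length(tq, 6L)  # 3 fields x {plain, truncated}

  th <- fixture_mesh()
  dq <- enumerate_variants(
    list(candidate_term("Glomerulonephritis", has_descriptor = TRUE,
                        fields = "tw", truncation = TRUE)),
    "pubmed", th
  )
  expect_length(dq, 6L)  # 2 text + {mh, majr} x {explode, noexp}
  kinds <- vapply(dq, function(q) q$root$kind, character(1))
  expect_identical(sum(kinds == "descriptor"), 4L)

  expect_error(
    enumerate_variants(list(candidate_term("No Such Heading", has_descriptor = TRUE)),
                       "pubmed", th),
    "unknown descriptor"
  )

  # duplicates collapse: same field listed twice
  dup <- enumerate_variants(
    list(candidate_term("nephrotic", fields = c("tw", "tw"), truncation = FALSE)),
    "pubmed"
  )
  expect_length(dup, 1L)
})

test_that("screening computes performance and orders by Youden with stable ties", {
  rows <- c(
    lapply(1:9, function(i) list(uid = paste0("R", i), words = "marker", relevant = TRUE)),
    list(list(uid = "R10", words = "quiet", relevant = TRUE)),
    lapply(1:5, function(i) list(uid = paste0("I", i), words = "marker", relevant = FALSE)),
    lapply(6:100, function(i) list(uid = paste0("I", i), words = "quiet", relevant = FALSE))
  )
  corpus <- term_corpus(rows)
  scr <- screen(list(parse_pubmed("marker[tw]")), corpus, NULL, develop_config())
  expect_length(scr, 1L)
  expect_equal(scr[[1]]$performance$sensitivity$estimate, 0.9)
  expect_equal(scr[[1]]$performance$specificity$estimate, 0.95)

  # a candidate retrieving nothing: sens 0, spec 1 -> survives the spec screen
  scr0 <- screen(list(parse_pubmed("absent[tw]")), corpus, NULL, develop_config())
  expect_equal(scr0[[1]]$performance$sensitivity$estimate, 0)
  expect_equal(scr0[[1]]$performance$specificity$estimate, 1)

  # equal-Youden candidates order by leaf count then text, reproducibly
  twoA <- parse_pubmed("marker[tw] OR marker[ti]")
  oneB <- parse_pubmed("marker[tiab]")
  scr2 <- screen(list(twoA, oneB), corpus, NULL, develop_config())
  expect_identical(to_string(scr2[[1]]$query), "marker[tiab]")
  expect_identical(scr2, screen(list(twoA, oneB), corpus, NULL, develop_config()))
})

test_that("a perfect marker yields a single-clause filter at 100/100", {
  rows <- c(
    lapply(1:10, function(i) list(uid = paste0("R", i), words = "perfect", relevant = TRUE)),
    lapply(1:50, function(i) list(uid = paste0("I", i), words = "noise", relevant = FALSE))
  )
  corpus <- term_corpus(rows)
  pool <- list(parse_pubmed("perfect[tw]"), parse_pubmed("noise[tw]"))
  out <- develop_filter(corpus, NULL, pool,
                        develop_config(screen_min_sens = 0, screen_min_spec = 0))
  best <- out[[1]]
  expect_identical(to_string(best$query), "perfect[tw]")
  expect_equal(best$performance$sensitivity$estimate, 1)
  expect_equal(best$performance$specificity$estimate, 1)
})

test_that("complementary terms are OR-combined to full sensitivity, matching exhaustive search", {
  rows <- c(
    lapply(1:10, function(i) list(uid = paste0("A", i), words = "alpha", relevant = TRUE)),
    lapply(1:10, function(i) list(uid = paste0("B", i), words = "beta", relevant = TRUE)),
    lapply(1:80, function(i) list(uid = paste0("I", i), words = "noise", relevant = FALSE))
  )
  corpus <- term_corpus(rows)
  pool <- list(parse_pubmed("alpha[tw]"), parse_pubmed("beta[tw]"),
               parse_pubmed("noise[tw]"))
  out <- develop_filter(corpus, NULL, pool,
                        develop_config(screen_min_sens = 0, screen_min_spec = 0,
                                       beam_width = 8, max_or_clauses = 2))
  best <- out[[1]]
  expect_equal(best$performance$sensitivity$estimate, 1)
  expect_equal(best$performance$specificity$estimate, 1)

  labels <- corpus_labels(corpus)
  masks <- lapply(pool, function(q) corpus_uids(corpus) %in% retrieve(q, corpus))
  expect_equal(youden(best$performance),
               exhaustive_best(masks, labels, max_clauses = 2L))
})

test_that("AND refinement lifts specificity above either single term", {
  set.seed(31)
  rows <- list()
  for (i in 1:30) {
    rows[[length(rows) + 1L]] <- list(uid = paste0("R", i),
                                      words = c("aterm", "bterm"), relevant = TRUE)
  }
  for (i in 1:200) {
    words <- c(if (runif(1) < 0.3) "aterm", if (runif(1) < 0.3) "bterm", "pad")
    rows[[length(rows) + 1L]] <- list(uid = paste0("I", i), words = words,
                                      relevant = FALSE)
  }
  corpus <- term_corpus(rows)
  pool <- list(parse_pubmed("aterm[tw]"), parse_pubmed("bterm[tw]"))
  out <- develop_filter(corpus, NULL, pool,
                        develop_config(screen_min_sens = 0, screen_min_spec = 0,
                                       beam_width = 4, max_or_clauses = 2))
  best <- out[[1]]
  expect_identical(best$query$root$op, "AND")
  expect_equal(best$performance$sensitivity$estimate, 1)

  # specificity matches direct counting and beats both single terms
  labels <- corpus_labels(corpus)
  singles <- vapply(pool, function(q) {
    mask <- corpus_uids(corpus) %in% retrieve(q, corpus)
    sum(!mask & !labels) / sum(!labels)
  }, numeric(1))
  both <- corpus_uids(corpus) %in%
    retrieve(parse_pubmed("aterm[tw] AND bterm[tw]"), corpus)
  expect_equal(best$performance$specificity$estimate,
               sum(!both & !labels) / sum(!labels))
  expect_gt(best$performance$specificity$estimate, max(singles))
})

test_that("beam search is deterministic and honors the specificity floor", {
  corpus <- random_corpus(150, seed = 17)
  th <- fixture_mesh()
  pool <- enumerate_variants(list(
    candidate_term("proteinuria", fields = c("tw", "tiab")),
    candidate_term("lupus", fields = "tw"),
    candidate_term("vasculitis", fields = "tw", truncation = FALSE)
  ), "pubmed", th)
  cfg <- develop_config(objective = "max_sens_given_spec", spec_floor = 0.5,
                        screen_min_sens = 0, screen_min_spec = 0, beam_width = 4)
  out1 <- develop_filter(corpus, th, pool, cfg)
  out2 <- develop_filter(corpus, th, pool, cfg)
  expect_identical(lapply(out1, function(cd) to_string(cd$query)),
                   lapply(out2, function(cd) to_string(cd$query)))
  if (!isTRUE(attr(out1, "infeasible"))) {
    expect_gte(out1[[1]]$performance$specificity$estimate, 0.5)
  }
  expect_error(
    develop_filter(corpus, th, pool,
                   develop_config(screen_min_sens = 0.99, screen_min_spec = 0.999)),
    "screening"
  )
})

test_that("the Pareto frontier equals a brute-force dominance scan", {
  mk <- function(se_x, se_n, sp_x, sp_n) {
    tab <- contingency_table(se_x, sp_n - sp_x, se_n - se_x, sp_x)
    filtercraft:::new_filter_candidate(parse_pubmed("x[tw]"), tab, performance(tab))
  }
  one <- mk(9, 10, 90, 100)
  expect_identical(pareto_frontier(list(one)), list(one))

  a <- mk(9, 10, 9, 10)   # se .9 sp .9
  b <- mk(8, 10, 8, 10)   # dominated
  expect_length(pareto_frontier(list(a, b)), 1L)

  set.seed(77)
  for (rep in 1:10) {
    cands <- lapply(1:12, function(i) mk(sample(0:20, 1), 20, sample(0:50, 1), 50))
    front <- pareto_frontier(cands)
    se <- vapply(cands, function(cd) cd$performance$sensitivity$estimate, numeric(1))
    sp <- vapply(cands, function(cd) cd$performance$specificity$estimate, numeric(1))
    brute <- cands[!vapply(seq_along(cands), function(i) {
      any(se >= se[i] & sp >= sp[i] & (se > se[i] | sp > sp[i]))
    }, logical(1))]
    expect_setequal(
      vapply(front, function(cd) paste(cd$table$a, cd$table$d), character(1)),
      vapply(brute, function(cd) paste(cd$table$a, cd$table$d), character(1))
    )
    # frontier is sorted by descending sensitivity
    fse <- vapply(front, function(cd) cd$performance$sensitivity$estimate, numeric(1))
    expect_true(all(diff(fse) <= 1e-12))
  }
})
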