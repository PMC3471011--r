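make_rec <- function(uid = "r1", title = "some plain title", abstract = "",
                     ...) {
  citation_record(uid, "JX", 2005, title, abstract, ...)
}

test_that("field scopes search the right parts of a citation", {
  rec <- make_rec(
    title = "Diabetic kidney disease and outcomes",
    abstract = "We measured albuminuria in this cohort",
    index_terms = list(index_term("Nephrotic Syndrome")),
    entry_term_strings = "minimal change disease"
  )
  th <- fixture_mesh()
  expect_true(matches(parse_pubmed("diabetic kidney[ti]"), rec))
  expect_false(matches(parse_pubmed("albuminuria[ti]"), rec))
  expect_true(matches(parse_pubmed("albuminuria[tiab]"), rec))
  # index-derived text is reachable through [tw]/.mp but not [tiab]
  expect_false(matches(parse_pubmed("nephrotic syndrome[tiab]"), rec))
  expect_true(matches(parse_pubmed("nephrotic syndrome[tw]"), rec))
  expect_true(matches(parse_ovid("nephrotic syndrome.mp", "ovid_medline"), rec))
  expect_true(matches(parse_pubmed("minimal change[tw]"), rec))  # entry string
  # phrases never straddle two index strings
  expect_false(matches(parse_pubmed("syndrome minimal[tw]"), rec))
})

test_that("a term appearing solely in the journal name never matches", {
  rec <- citation_record("r1", "Kidney International", 2005, "unrelated words")
  expect_false(matches(parse_pubmed("kidney[tw]"), rec))
  expect_false(matches(parse_ovid("kidney.mp", "ovid_medline"), rec))
  expect_true(matches(parse_pubmed("kidney[jn]"), rec))
})

test_that("phrases, truncation, wildcards, and hyphen splitting behave", {
  rec <- make_rec(title = "anti-glomerular basement membrane antibodies in microscopic polyangiitis")
  expect_true(matches(parse_pubmed("anti-glomerular[tw]"), rec))
  expect_true(matches(parse_pubmed("glomerular basement[tw]"), rec))  # hyphen split
  expect_false(matches(parse_pubmed("antiglomerular[tw]"), rec))     # closed form distinct
  expect_true(matches(parse_pubmed("polyang*[tw]"), rec))
  expect_false(matches(parse_pubmed("polyangX*[tw]"), rec))
  expect_true(matches(parse_ovid("polyang?itis.mp", "ovid_medline"), rec))
  rec2 <- make_rec(title = "microscopic polyangitis case report")
  expect_true(matches(parse_ovid("polyang?itis.mp", "ovid_medline"), rec2))
  rec3 <- make_rec(title = "polyangiiitis misspelled thrice")
  expect_false(matches(parse_ovid("polyang?itis.mp", "ovid_medline"), rec3))
  # multi-token truncation: each $ token is a prefix
  rec4 <- make_rec(title = "glomerular basement membranes were thickened")
  expect_true(matches(parse_ovid("glomerul$ basement membrane$.tw", "ovid_embase"), rec4))
})

test_that("descriptor leaves respect explosion, major focus, and subheadings", {
  th <- fixture_mesh()
  rec <- make_rec(index_terms = list(
    index_term("Glomerulonephritis, IGA", major = FALSE, subheadings = "therapy")
  ))
  expect_true(matches(parse_pubmed("Kidney Diseases[mh]"), rec, th))
  expect_false(matches(parse_pubmed("Kidney Diseases[mh:noexp]"), rec, th))
  expect_false(matches(parse_pubmed("Kidney Diseases[majr]"), rec, th))
  expect_true(matches(parse_pubmed('"Glomerulonephritis, IGA"[mh:noexp]'), rec, th))
  expect_true(matches(parse_pubmed("Glomerulonephritis, IGA/therapy[mh]"), rec, th))
  expect_false(matches(parse_pubmed("Glomerulonephritis, IGA/diagnosis[mh]"), rec, th))
  recM <- make_rec(index_terms = list(index_term("Glomerulonephritis, IGA", major = TRUE)))
  expect_true(matches(parse_pubmed("Kidney Diseases[majr]"), recM, th))
  # Ovid equivalents agree
  expect_true(matches(parse_ovid("exp Kidney Diseases/", "ovid_medline"), rec, th))
  expect_false(matches(parse_ovid("Kidney Diseases/", "ovid_medline"), rec, th))
  # unresolvable descriptor errors
  expect_error(matches(parse_pubmed("No Such Heading[mh]"), rec, th), "unknown descriptor")
})

test_that("adjacency respects order for adj and window for adjN", {
  q_adj <- parse_ovid("(diabetic adj (kidney or renal)).mp", "ovid_medline")
  expect_true(matches(q_adj, make_rec(title = "Diabetic kidney disease and outcomes")))
  expect_true(matches(q_adj, make_rec(title = "early diabetic renal lesions")))
  expect_false(matches(q_adj, make_rec(title = "kidney diabetic mismatch order")))
  expect_false(matches(q_adj, make_rec(title = "diabetic chronic kidney gap")))
  q2 <- parse_ovid("(chronic adj2 (kidney or renal)).mp", "ovid_medline")
  expect_true(matches(q2, make_rec(title = "chronic kidney disease")))
  expect_true(matches(q2, make_rec(title = "chronic severe kidney disease")))
  expect_true(matches(q2, make_rec(title = "kidney was chronic")))  # either order
  expect_false(matches(q2, make_rec(title = "chronic and very severe kidney disease")))
})

test_that("classification codes match exactly through .ec", {
  rec <- make_rec(classification_codes = c("Urology and Nephrology", "49.5"))
  expect_true(matches(parse_ovid('"Urology and nephrology".ec', "ovid_embase"), rec))
  expect_false(matches(parse_ovid('"Urology".ec', "ovid_embase"), rec))
})

test_that("retrieve agrees with matches and with Boolean set algebra", {
  th <- fixture_mesh()
  one <- labeled_corpus(list(make_rec(title = "nephrotic syndrome relapse")))
  q <- parse_pubmed("nephrotic[tw]")
  expect_identical(retrieve(q, one, th),
                   if (matches(q, one$records[[1]], th)) "r1" else character())
  expect_identical(retrieve(parse_pubmed("absentterm[tw]"), one, th), character())

  for (seed in 1:50) {
    corpus <- random_corpus(40, seed = seed)
    qa <- random_query("pubmed"); qb <- random_query("pubmed")
    a <- retrieve(qa, corpus, th); b <- retrieve(qb, corpus, th)
    or_q <- filtercraft:::new_query(filtercraft:::new_bool("OR", list(qa$root, qb$root)), "pubmed")
    and_q <- filtercraft:::new_query(filtercraft:::new_bool("AND", list(qa$root, qb$root)), "pubmed")
    not_q <- filtercraft:::new_query(filtercraft:::new_bool("NOT", list(qa$root, qb$root)), "pubmed")
    expect_setequal(retrieve(or_q, corpus, th), union(a, b))
    expect_setequal(retrieve(and_q, corpus, th), intersect(a, b))
    expect_setequal(retrieve(not_q, corpus, th), setdiff(a, b))
  }
})

test_that("retrieval is invariant to record order", {
  th <- fixture_mesh()
  corpus <- random_corpus(60, seed = 3)
  shuffled <- labeled_corpus(rev(corpus$records), corpus$labels)
  for (i in 1:5) {
    q <- random_query("pubmed")
    expect_setequal(retrieve(q, corpus, th), retrieve(q, shuffled, th))
  }
})
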