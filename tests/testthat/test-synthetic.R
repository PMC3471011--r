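small_config <- function(...) {
  generator_config(n_journals = 5L, articles_per_journal = 100L,
                   prevalence = 0.2, seed = 7L, ...)
}

test_that("zero prevalence yields an all-irrelevant corpus", {
  cfg <- generator_config(n_journals = 2L, articles_per_journal = 50L,
                          prevalence = 0, profiles = list(
                            term_profile("marker", p_text_rel = 1, p_text_irr = 0)
                          ), seed = 3L)
  corpus <- generate(cfg)
  expect_false(any(corpus$labels))
})

test_that("a deterministic seed gives byte-identical JSONL output", {
  cfg <- small_config()
  th <- fixture_mesh()
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(generate(cfg, th), f1)
  write_corpus_jsonl(generate(cfg, th), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("generated label prevalence stays within Monte-Carlo bounds", {
  cfg <- small_config()
  corpus <- generate(cfg, fixture_mesh())
  n <- length(corpus$records)
  pi0 <- cfg$prevalence
  expect_lt(abs(mean(corpus$labels) - pi0), 3 * sqrt(pi0 * (1 - pi0) / n))
})

test_that("a noiseless perfect marker gives an empirically perfect filter", {
  cfg <- generator_config(n_journals = 2L, articles_per_journal = 100L,
                          prevalence = 0.3, indexing_dropout = 0,
                          profiles = list(
                            term_profile("markerword", p_text_rel = 1, p_text_irr = 0)
                          ), seed = 9L)
  corpus <- generate(cfg)
  cand <- evaluate_filter(parse_pubmed("markerword[tw]"), corpus)
  expect_equal(cand$performance$sensitivity$estimate, 1)
  expect_equal(cand$performance$specificity$estimate, 1)
})

test_that("planted single-term accuracy tracks the class-conditional rates", {
  cfg <- generator_config(n_journals = 20L, articles_per_journal = 250L,
                          prevalence = 0.05,
                          profiles = list(
                            term_profile("plantedterm", p_text_rel = 0.9, p_text_irr = 0.05)
                          ), seed = 21L)
  corpus <- generate(cfg)
  cand <- evaluate_filter(parse_pubmed("plantedterm[tw]"), corpus)
  n_rel <- sum(corpus$labels)
  n_irr <- sum(!corpus$labels)
  expect_lt(abs(cand$performance$sensitivity$estimate - 0.9),
            3 * sqrt(0.9 * 0.1 / n_rel))
  expect_lt(abs(cand$performance$specificity$estimate - 0.95),
            3 * sqrt(0.05 * 0.95 / n_irr))
})

test_that("expected performance follows the closed forms", {
  cfg <- generator_config(profiles = list(
    term_profile("alphaword", p_text_rel = 0.9, p_text_irr = 0.05),
    term_profile("betaword", p_text_rel = 0.5, p_text_irr = 0.10)
  ))
  single <- expected_performance(parse_pubmed("alphaword[tw]"), cfg)
  expect_equal(unname(single["sensitivity"]), 0.9)
  expect_equal(unname(single["specificity"]), 0.95)

  both <- expected_performance(parse_pubmed("alphaword[tw] OR betaword[tw]"), cfg)
  expect_equal(unname(both["sensitivity"]), 1 - 0.1 * 0.5)  # 0.95
  expect_equal(unname(both["specificity"]), 0.95 * 0.90)

  conj <- expected_performance(parse_pubmed("alphaword[tw] AND betaword[tw]"), cfg)
  expect_equal(unname(conj["sensitivity"]), 0.45)

  excl <- expected_performance(parse_pubmed("alphaword[tw] NOT betaword[tw]"), cfg)
  expect_equal(unname(excl["sensitivity"]), 0.9 * 0.5)

  # spelling-variant shares: a wildcard covering both surfaces gets the
  # full probability, an exact spelling only its weighted share
  cfg2 <- generator_config(profiles = list(
    term_profile(c("polyangiitis", "polyangitis"), weights = c(0.7, 0.3),
                 p_text_rel = 0.4, p_text_irr = 0.01)
  ))
  wild <- expected_performance(parse_ovid("polyang?itis.mp", "ovid_medline"), cfg2)
  expect_equal(unname(wild["sensitivity"]), 0.4)
  exact <- expected_performance(parse_ovid("polyangiitis.mp", "ovid_medline"), cfg2)
  expect_equal(unname(exact["sensitivity"]), 0.4 * 0.7)

  expect_error(expected_performance(parse_pubmed("unknownterm[tw]"), cfg),
               "does not map")
  expect_error(
    expected_performance(parse_ovid("(a adj b).mp", "ovid_medline"), cfg),
    "adjacency"
  )
})

test_that("descriptor leaves map through indexing probabilities and dropout", {
  th <- fixture_mesh()
  cfg <- generator_config(indexing_dropout = 0.1, profiles = list(
    term_profile("glomerulonephritis", p_text_rel = 0.6, p_text_irr = 0.02,
                 descriptor = "Glomerulonephritis",
                 p_index_rel = 0.6, p_index_irr = 0.03,
                 p_major_given_indexed = 0.5)
  ))
  mh <- expected_performance(parse_pubmed("Glomerulonephritis[mh]"), cfg, th)
  expect_equal(unname(mh["sensitivity"]), 0.6 * 0.9)
  majr <- expected_performance(parse_pubmed("Glomerulonephritis[majr]"), cfg, th)
  expect_equal(unname(majr["sensitivity"]), 0.6 * 0.9 * 0.5)
  # exploding an ancestor reaches the planted descriptor
  anc <- expected_performance(parse_pubmed("Kidney Diseases[mh]"), cfg, th)
  expect_equal(unname(anc["sensitivity"]), 0.54)
  expect_error(expected_performance(parse_pubmed("Kidney Diseases[mh:noexp]"), cfg, th),
               "does not map")
})

test_that("empirical retrieval agrees with expected performance across random queries", {
  th <- fixture_mesh()
  cfg <- generator_config(n_journals = 10L, articles_per_journal = 300L,
                          prevalence = 0.3, seed = 33L)
  corpus <- generate(cfg, th)
  n_rel <- sum(corpus$labels)
  n_irr <- sum(!corpus$labels)
  # one atom per independent generative event: three text occurrences
  # (the indexed profile through [tiab], which does not search index-term
  # names) and one indexing event; any pair is independent under the model
  atoms <- c("proteinuria[tw]", "glomerulonephritis[tiab]", "polyang*[tw]",
             "Glomerulonephritis[mh]")
  set.seed(91)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    chosen <- sample(atoms, k)
    op <- sample(c("OR", "AND"), 1)
    q <- parse_pubmed(paste(chosen, collapse = paste0(" ", op, " ")))
    ep <- expected_performance(q, cfg, th)
    cand <- evaluate_filter(q, corpus, th)
    se_tol <- 3 * sqrt(max(ep["sensitivity"] * (1 - ep["sensitivity"]), 0.002) / n_rel)
    sp_tol <- 3 * sqrt(max(ep["specificity"] * (1 - ep["specificity"]), 0.002) / n_irr)
    expect_lt(abs(cand$performance$sensitivity$estimate - ep["sensitivity"]), se_tol)
    expect_lt(abs(cand$performance$specificity$estimate - ep["specificity"]), sp_tol)
  }
})

test_that("YAML configs round-trip into generator configurations", {
  path <- system.file("extdata", "generator_default.yaml", package = "filtercraft")
  cfg <- read_generator_config(path)
  expect_identical(cfg$n_journals, 20L)
  expect_identical(cfg$prevalence, 0.05)
  expect_length(cfg$profiles, 3L)
  expect_identical(cfg$profiles[[3]]$surfaces, c("polyangiitis", "polyangitis"))
  ref <- generator_config()
  expect_equal(cfg$profiles[[1]]$p_text_rel, ref$profiles[[1]]$p_text_rel)
})

test_that("journal prevalence multipliers shift per-journal relevance", {
  cfg <- generator_config(n_journals = 2L, articles_per_journal = 400L,
                          prevalence = 0.2,
                          journal_prevalence_multiplier = c(0, 2),
                          profiles = list(), seed = 13L)
  corpus <- generate(cfg)
  labs <- corpus$labels
  j <- vapply(corpus$records, `[[`, character(1), "journal_id")
  expect_identical(sum(labs[j == "J001"]), 0L)
  p2 <- mean(labs[j == "J002"])
  expect_lt(abs(p2 - 0.4), 3 * sqrt(0.4 * 0.6 / 400))
})
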