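# filtercraft

Tools for developing and validating Boolean **search filters** ("hedges")
for bibliographic databases, built around the diagnostic-test framework
used to derive topic filters for glomerular disease in PubMed, Ovid
Medline, and Embase.

Finding the glomerular-disease literature is hard: relevant trials and
reviews are scattered across nephrology, internal-medicine, and
transplantation journals, and indexing is inconsistent ("membranous
nephropathy", "glomerulopathy", "nephrotic syndrome", ...). A search
filter is a pre-tested Boolean query — typically a large OR of free-text
terms, truncated stems, and controlled-vocabulary headings — that
restricts a database to a topical subset. Filter development treats the
filter like a diagnostic test: retrieval is scored against a manually
labeled reference standard in a 2×2 table

|                 | relevant | non-relevant |
|-----------------|----------|--------------|
| retrieved       | a        | b            |
| not retrieved   | c        | d            |

with sensitivity a/(a+c), specificity d/(b+d), precision a/(a+b), and
accuracy (a+d)/n, each with a confidence interval; candidate terms are
screened one at a time and then combined with OR/AND/NOT to maximize
sensitivity or specificity; the selected filters are re-scored once on a
held-out validation set split from the development set **at the journal
level**.

`filtercraft` implements that whole workflow as reusable parts:

* **Query engine** — parsers for the PubMed dialect (`nephropath*[tw]`,
  `"Kidney Glomerulus"[majr:noexp]`) and the Ovid dialect
  (`glomerulo$.mp`, `exp *Kidney Diseases/`, `polyang?itis.mp`,
  `(diabetic adj (kidney or renal)).mp`) into one AST, plus an evaluator
  with faithful field semantics: `[tiab]`/`.tw` search title+abstract,
  `[tw]`/`.mp` additionally search index-term names, subheadings, and
  entry terms, `.ec` matches classification codes, and a term appearing
  solely in the journal name never matches.
* **Thesaurus** — MeSH-like/Emtree-like trees with dot-coded tree numbers,
  entry-term synonymy, and explosion (a heading plus all descendants);
  toy vocabularies covering every heading in the published filters ship
  with the package.
* **Diagnostics** — contingency tables, the four accuracy metrics with
  Wald or Wilson intervals, Cohen's κ for reader calibration, and the
  2×2-inversion utilities (`invert_to_prevalence()`, `implied_accuracy()`)
  that recover prevalence and accuracy from a printed
  (sensitivity, specificity, precision) row.
* **Filter development** — candidate-variant enumeration (fields ×
  truncation × major focus × explosion), single-term screening, and a
  deterministic beam search that grows OR-of-clause filters (clauses are
  atoms or two-way conjunctions) under sensitivity-, specificity-, or
  Youden-optimal objectives, with a Pareto frontier over the results.
* **Synthetic corpora** — a generator that plants term profiles with
  class-conditional text and indexing probabilities into labeled journal
  clusters, and a closed-form `expected_performance()` for any AND/OR/NOT
  query over the planted events, so the optimizer can be tested against a
  known generative optimum.
* **Published filters** — the six glomerular-disease filters (PubMed /
  Ovid Medline / Embase × high-sensitivity / high-specificity) as
  verbatim, parseable fixtures: `load_published_filter()`.

## Worked example

Generate a labeled corpus under the package's reference condition (5,000
records in 20 journals, 5% relevant, three planted term profiles), split
it two-to-one by journal, develop a sensitivity-optimized filter on the
development view, and validate it once:

```r
library(filtercraft)
th <- toy_mesh()
corpus <- generate(generator_config(seed = 2026), th)
split <- split_by_journal(corpus, c(2, 1), seed = 2026)
dev <- corpus_view_journals(corpus, split$development_journals)
val <- corpus_view_journals(corpus, split$validation_journals)

pool <- enumerate_variants(
  list(candidate_term("proteinuria", fields = c("tw", "tiab")),
       candidate_term("glomerulonephritis", has_descriptor = TRUE, fields = "tw"),
       candidate_term("polyangiitis", fields = "tw", stem = "polyang")),
  "pubmed", th)

best <- develop_filter(dev, th, pool,
  develop_config(objective = "max_sens_given_spec", spec_floor = 0.90))[[1]]
best
#> (proteinuria*[tiab] OR glomerulonephriti*[tw] OR polyangiitis[tw])
#>   se 98.4%  sp 90.1%  ppv 37.1%  acc 90.6%  (a=179 b=303 c=3 d=2765)
evaluate_filter(best$query, val, th)
#> (proteinuria*[tiab] OR glomerulonephriti*[tw] OR polyangiitis[tw])
#>   se 98.8%  sp 90.3%  ppv 34.1%  acc 90.7%  (a=84 b=162 c=1 d=1503)
```

The beam search found the three planted signals, kept specificity above
the 0.90 floor, and the filter's validation performance matches its
development performance to within sampling noise — while precision drops
on the validation view, the same behavior filter studies report when
moving to a pool with fewer relevant articles.

The published filters are ordinary queries:

```r
q <- load_published_filter("pubmed_high_sensitivity")
count_leaves(q)
#> [1] 52
```

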