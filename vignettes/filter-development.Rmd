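---
title: "Developing and validating Boolean search filters with filtercraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating Boolean search filters with filtercraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filtercraft)
```

## The problem and the model

A topic search filter is a Boolean query meant to carve a bibliographic
database down to a subject area — here, glomerular disease — so that a
clinician's own search terms run against a pre-enriched subset. Filter
development is treated exactly like the evaluation of a diagnostic test.
A reference standard assigns every article in a sample of journals a
binary relevance label; a candidate filter retrieves a subset; the 2×2
cross-classification of retrieval against relevance yields

* sensitivity $a/(a+c)$ — the fraction of relevant articles retrieved,
* specificity $d/(b+d)$ — the fraction of non-relevant articles excluded,
* precision $a/(a+b)$ — the fraction of retrieved articles that are relevant,
* accuracy $(a+d)/n$.

Because all four metrics are functions of one table, they are mutually
redundant: given a prevalence $p$, accuracy $= se \cdot p + sp\,(1-p)$,
and precision determines $p$ through the identity
$p = \mathrm{ppv}\,(1-sp)\,/\,[se\,(1-\mathrm{ppv}) + \mathrm{ppv}\,(1-sp)]$.
`invert_to_prevalence()` and `implied_accuracy()` expose these
identities; they are also the package's consistency check on published
performance rows (an accuracy recomputed from the printed sensitivity,
specificity, and precision must match the printed accuracy at the
printed precision — for rows whose rounded inputs carry enough
information to do so).

Development and validation are separated **at the journal level**: the
journal set is randomly partitioned (by default two-to-one) and every
article follows its journal. This is deliberately stricter than an
article-level split — a filter that merely memorized the house style of
particular journals would validate poorly — and it is why the package
splits journals, not records (`split_by_journal()`), with the 2:1 ratio
applying to journal counts. The observed article counts on either side
are an outcome, not a constraint. Validation data are consumed exactly
once, by an explicit `evaluate_filter()` call; nothing in the
development path touches them.

## The query engine

Both supported dialects parse into one AST of term leaves, Boolean
nodes, and adjacency nodes, evaluated per record over token sequences.

**Tokenization.** Text is lowercased, split on whitespace and hyphens,
and stripped of other punctuation. Hyphen-splitting makes
`anti-glomerular` a two-token phrase, so the hyphenated and spaced forms
of a compound match each other while the closed form
(`antiglomerular`) stays a distinct search term — mirroring how the
databases treat these variants and why published filters enumerate both.

**Field semantics.** `ti` searches the title; `[tiab]` and Ovid `.tw`
search title and abstract; `[tw]` and Ovid `.mp` additionally search the
indexing-derived text of the record — descriptor names, subheadings, and
entry-term strings — each as its own token sequence, so a phrase can
never straddle two index terms. The journal name is searchable only
through `jn`: a term appearing solely in the journal name satisfies
nothing else, implementing the rule that journal titles must not carry a
filter. `.ec` matches Embase-style classification codes as exact
(case-insensitive) strings. Internally Ovid `.tw` is stored as the
`tiab` field and `[tw]`/`.mp` share one wide scope; rendering restores
each dialect's surface syntax, and `parse(to_string(q))` is AST-equal to
`q` for every parseable query.

**Truncation and wildcards.** A trailing `*` (PubMed) or `$` (Ovid)
makes the token a prefix match; multi-token phrases may truncate any
token (`glomerul$ basement membrane$`). `?` matches zero or one
character, so `polyang?itis` covers both the double-i and single-i
spellings; British/American variants are otherwise handled by explicit
enumeration in term lists, not by an automatic variant engine.

**Adjacency.** `adj` (and `adj1`) requires the left operand immediately
before the right; `adjN` for `N ≥ 2` allows up to `N − 1` intervening
tokens in either order. The operators are undefined in the source
strategies themselves; these are the conventional Ovid readings, chosen
once and property-tested against an exhaustive token-pair scan. Either
side may be an OR-group of terms, the only shape that occurs in printed
filters.

**Explosion.** A descriptor search with explosion matches records
indexed with the heading or any descendant, where descendant means "any
tree number extends one of mine by at least one dot segment". PubMed
`[mh]`/`[majr]` explode by default with `:noexp` opting out; a bare Ovid
`Name/` does not explode and `exp` opts in — an asymmetry forced by the
two interfaces behaving that way in practice (the equivalent single-term
filters `Kidney Diseases[mh]` and `exp Kidney Diseases/` retrieve
identically). Real MeSH and Emtree are licensed and large; the package
ships ~30-node toy vocabularies covering every heading named in the six
published filters. All explosion logic is exercised on those and on
randomly generated trees; nothing is claimed about retrieval performance
under the full vocabularies.

**Atom counting.** `count_leaves()` counts text terms, descriptor terms,
and each alternative inside an adjacency OR-group as one atom each, so
`(diabetic adj (kidney or renal))` contributes three. This is the
convention under which the published high-sensitivity filters comprise
"over 50 terms" (the shipped PubMed and Medline high-sensitivity
fixtures both count 52, the high-specificity pair 66).

## Filter development

The published combination algorithm is described only as
computer-implemented selective use of OR, AND, and NOT. Every printed
filter, however, has the same shape: one large OR whose clauses are
single atoms or two-way conjunctions of small OR-groups. The package
therefore searches exactly that space with a deterministic beam search:

1. **Enumeration** (`enumerate_variants()`): each candidate term expands
   into allowed fields × {plain, truncated-at-stem}, and descriptor
   terms additionally into {heading, major-topic} × {exploded,
   unexploded}. When no explicit stem is given, the truncated variant
   strips a trailing "s", then "y"/"ic", from the final token (stems
   shorter than four characters are left alone) — a minimal, documented
   heuristic standing in for hand-chosen stems.
2. **Screening** (`screen()`): every variant is evaluated on the
   development corpus; candidates are kept when sensitivity ≥ 0.10 *or*
   specificity ≥ 0.90 (defaults — keep broadly sensitive terms and
   highly specific ones; no screening thresholds are published),
   and ranked by Youden index (sensitivity + specificity − 1) with ties
   broken by atom count, then query text, so ordering is reproducible.
3. **Combination** (`develop_filter()`): the beam starts from the best
   single candidate under the objective. Each step proposes adding one
   OR clause (the sensitivity direction) and, when enabled, AND-refining
   or NOT-excluding an existing clause (the specificity direction);
   the `beam_width` best states satisfying the objective's floor are
   kept; the search stops when the best improvement falls below
   `epsilon` (default 10⁻⁴) or `max_or_clauses` is reached. Monotonicity
   is asserted at every step: an OR addition never lowers sensitivity or
   raises specificity, and a refinement never does the reverse. State
   retrieval sets are composed by set algebra over cached per-atom
   retrieval masks; the equivalence of that composition with direct
   evaluation is itself a tested property of the engine.

Three objectives are provided: maximize sensitivity subject to a
specificity floor, the converse, and balanced Youden. Youden's index is
the package's balanced trade-off statistic — the development procedure's
own choice, since no trade-off statistic is published. NOT is available
but off by default: no printed filter uses it. Precision is reported and
used as a Pareto tie-break (`pareto_frontier()`) but never as a floor —
whether the original selection imposed precision floors or inspected
precision afterwards is unstated, so the package exposes it without
constraining on it.

On small pools the beam provably matches exhaustive enumeration (a test
compares it against brute force over every ≤ 3-clause filter from pools
of ≤ 8 candidates); at realistic pool sizes exhaustive search over the
~10⁶ filters the original study screened is out of reach of a desk
machine and the beam is the intended tool.

## The synthetic reference standard

The original 22,992-article manually labeled corpus is not public, so
the package generates labeled corpora with known structure
(`generate()`): records are assigned to journals round-robin; relevance
is Bernoulli with configurable prevalence (optionally modulated by a
per-journal multiplier, off by default); and each of a set of **term
profiles** independently contributes a text occurrence (one surface form
chosen by weight, inserted at a random position of title or abstract
with equal probability) and an indexing event (the profile's descriptor,
thinned by an indexing-dropout rate, with a major-topic flag), all with
class-conditional probabilities. Filler tokens come from a vocabulary
disjoint from every profile surface, so planted signal is unambiguous.
A fixed seed makes the corpus byte-identical across runs (one named
Mersenne-Twister stream).

Class-conditional independence across profiles is what makes expected
performance closed-form: for a query over planted events,
$P(\mathrm{OR}) = 1 - \prod(1 - p_i)$, $P(\mathrm{AND}) = \prod p_i$,
$P(A\ \mathrm{NOT}\ B) = p_A(1 - p_B)$, evaluated separately in each
class (`expected_performance()`). One subtlety the closed form carries:
the wide `[tw]`/`.mp` scope also searches index-term names, so for those
fields a text leaf whose phrase matches a profile's descriptor name gets
the indexing probability OR-ed into its match probability; `[tiab]`
leaves stay text-only. Two leaves over the *same* planted event (for
example the same term through `[tw]` and `[tiab]`, or a heading and its
major-topic restriction) are not independent, and expected values for
queries combining them are not meaningful — the test suite's
Monte-Carlo-versus-closed-form comparisons use one leaf per event.
Title-only and classification-code fields are excluded from the closed
form (the placement model would need extra structure), and adjacency has
no closed form.

The package's reference condition, chosen once: 20 journals × 250
articles (5,000 records), 5% prevalence — echoing the lower relevant
fraction of a validation pool — with three planted profiles of
decreasing strength (text rates 0.9/0.05, 0.6/0.02, 0.4/0.01, the
second also indexed at 0.6/0.03 with 10% dropout and a 0.5 major-topic
rate, the third with a 70/30 spelling-variant pair). What passing tests
on such corpora show is that the engine, statistics, and optimizer are
correct *under the generative model*; they do not show that toy
vocabularies or independent planted terms reproduce the term
co-occurrence, indexing practice, or prevalence structure of the real
literature, and no such claim is made.

A note on recovery testing: with several strong planted terms at
n = 5,000, the top few filters can be analytic near-ties (expected
Youden gaps below sampling noise), in which case "the" generative
optimum is not identifiable from one corpus and different near-optimal
filters legitimately win under different noise realizations. The
planted-recovery test therefore uses a single-profile condition, where
the optimum is unique and well separated, and checks optimizer-vs-
exhaustive agreement separately on the richer three-profile corpus.

## Statistical choices

* **Intervals.** Wald is the default — published filter tables print
  symmetric intervals consistent with it — with Wilson available by
  flag. At $\hat p \in \{0, 1\}$ the Wald interval collapses to the
  point and is flagged; Wilson is the sensible choice there and never
  leaves $[0,1]$. Both are hand-coded closed forms (the base-R
  `prop.test()` interval adds a continuity correction that printed
  tables do not show).
* **Undefined metrics** (zero denominator) are reported as `NA`, never
  as 0.
* **Percent formatting** rounds half away from zero to one decimal,
  matching printed tables (`percent1()`).
* **Cohen's κ** is the two-rater, two-category chance-corrected
  agreement used for reader calibration; when both raters are constant
  and equal, expected agreement is 1 and κ is undefined (`NA` with a
  warning). Multi-rater generalizations are out of scope.
* **Consensus labels** take the majority across readers; an exact tie is
  an error — the calibration design assumes readers resolve
  disagreements, and inventing a tie rule would silently change the
  reference standard.

## Problem sizes in the test suite

The suite generates everything it needs at run time: oracle-equivalence
runs 50 random 200-record corpora × 100 random queries each against a
naive set-algebra/token-scan evaluator (zero disagreements required);
monotonicity properties run on 20 random corpora; recovery and
Monte-Carlo-agreement tests use 5,000- and 3,000-record synthetic
corpora; interval coverage uses 10,000 seeded binomial draws at
n = 500, p = 0.9. These sizes were chosen to give the property tests
real bite while keeping the default suite comfortably interactive.

## Known limitations

* No automatic PubMed term mapping: untagged PubMed terms are a parse
  error rather than silently translated; Ovid multi-line search-history
  syntax, date/language limits, and stopword handling are unsupported.
* Subheading support covers a single optional subheading per descriptor
  leaf; subheading-qualified candidate generation is not enumerated.
* Toy vocabularies stand in for MeSH/Emtree; per-database record subsets
  share one journal split (separate per-database splits are not
  modelled, matching the development design's single split).
* The synthetic generator does not attempt realistic natural-language
  abstracts or dependent term co-occurrence.
* Live database searches (and therefore date-bound retrieval counts)
  are out of scope; the CLI `apply` subcommand demonstrates the
  filter-plus-user-query workflow on local corpora instead.
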