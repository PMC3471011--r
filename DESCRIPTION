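Package: filtercraft
Title: Development and Validation of Boolean Bibliographic Search Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building and validating Boolean search filters
    (hedges) for bibliographic databases, modelled on the diagnostic-test
    framework used to derive topic filters for PubMed, Ovid Medline, and
    Embase. Provides parsers and an evaluator for PubMed-dialect and
    Ovid-dialect queries (field tags, truncation, wildcards, adjacency,
    controlled-vocabulary explosion against MeSH-like and Emtree-like
    thesauri), journal-level development/validation splitting of labeled
    citation corpora, contingency-table accuracy statistics with Wald and
    Wilson intervals and Cohen's kappa, a beam-search optimizer that
    combines single-term filters into multi-term filters, a synthetic
    labeled-corpus generator with closed-form expected performance, and six
    published glomerular-disease filters shipped as executable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
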