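Package: generex
Title: Unsupervised Pattern Induction for Literature-Derived Gene
    Regulation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Bootstrapped generation of gene-regulation extraction patterns
    from a small seed set, weighted pattern-based extraction of
    transcription-factor to target-gene sentences from abstract corpora,
    and construction of layered gene regulatory networks. Includes
    dictionary-based tagging of transcription factors, genes and action
    words (with homonym priority and abbreviation long-form masking),
    wildcard token patterns induced from three templates with
    subset-merging and frequency thresholding, a linguistic-feature
    ranking of extracted sentences, iterated network expansion with
    frequency-based confidence, and a seeded synthetic-corpus generator
    with ground-truth scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
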