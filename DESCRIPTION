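Package: gcdecode
Title: Grammar-Constrained Decoding for Nested Template Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for structured information extraction with
    grammar-constrained decoding, aimed at slot filling of nested
    clinical-trial (PICO-style) templates from abstract text. Provides a
    declarative template-schema model with tag-based linearization of
    nested instances, a deterministic incremental parser that exposes the
    accepted-next-token set and the corresponding vocabulary mask at every
    generation step, greedy and grammar-constrained decoding loops over an
    abstract scorer interface, pointer-generator distribution mixing with
    max or sum attention aggregation, and an evaluator that aligns
    predicted to gold template instances by maximising micro-F1 with
    normalized-Levenshtein slot matching. Mock scorers and synthetic
    schema/instance/document generators make every component testable
    without a trained model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
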