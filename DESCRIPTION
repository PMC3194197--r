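Package: hgvsparser
Title: Parsing, Syntax Checking and Generation of HGVS Sequence Variant
    Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A formal-grammar toolkit for the Human Genome Variation Society
    (HGVS) sequence variant nomenclature. Implements recursive-descent
    parsers for the DNA/RNA-level grammar (top rule "Var") and the
    protein-level grammar (top rule "ProteinVar"), including allele sets,
    mosaic (/) and chimeric (//) separators, exclusive-or (^) combinations,
    nested sub-allele changes in curly braces, LRG transcript/protein
    suffixes, upstream/downstream (u/d) offsets, and legacy deviation rules
    (IVS/EX) plus lenient text-mining substitution operators (/, ->, -->).
    Provides a syntax checker with 0-based halt-position reporting and batch
    mode, canonical serialization back to description strings, structured
    parse-tree export as JSON, a grammar-as-data export, a Chomsky normal
    form transform with a CYK membership oracle for verifying the parser,
    and a seeded grammar-driven random description generator for fuzzing
    and test fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
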