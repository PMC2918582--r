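Package: s3db
Title: Two-Tier RDF Data Management with Propagated User-Operator States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An implementation of the S3DB core model for biomedical
    semantic data management: a typed RDF design pattern that separates
    the description of a domain (rules) from its observational
    instantiation (statements), built from seven entity kinds and twelve
    validated relationships.  On top of the schema store sits a finite
    state machinery for user operators: dominant/recessive state symbols,
    set merging, multi-operator state migration along a Boolean
    transition matrix, and fixed-point percolation over instance graphs,
    yielding fine-grained permission resolution (View/Edit/Use).  Stores
    round-trip through a Turtle/N3 dialect, a seeded generator produces
    arbitrary valid instance graphs for testing, and a command-line
    interface wraps the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
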