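Package: qchemlog
Title: Semantic Conversion and Indexing of Quantum-Chemistry Logfiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative template engine that parses record-oriented
    quantum-chemistry logfiles (Gaussian-style dialects) into a typed
    semantic document tree, a transformation layer that normalizes the
    tree into the compchem convention with dictionary-resolved terms and
    units, and a desk-scale index for chemically and numerically
    searchable collections of calculation results.  Includes a
    deterministic generator of synthetic logfiles with recorded ground
    truth so the whole stack is testable without external data, and a
    batch command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
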