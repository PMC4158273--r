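Package: inchilink
Title: Connectivity-Level Compound Cross-Referencing with InChI Layer Parsing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained compound cross-reference registry keyed on the
    Standard InChI, extended with a first-InChIKey-hash-block (FIKHB)
    parent-child hierarchy so that queries link molecules sharing atom
    connectivity across salt, mixture, stereoisomeric, isotopic and
    protonation variants. Provides layer-level Standard InChI parsing and
    multi-component splitting, InChIKey/FIKHB handling with pluggable key
    providers (an Open Babel wrapper and a hermetic surrogate), a loader
    maintaining the FIKHB hierarchy, a connectivity search engine driven by
    eight user criteria with per-layer difference annotation, a brute-force
    reference search for verification, a deterministic synthetic fixture
    generator, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
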