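Package: dnadesign
Title: Combinatorial DNA Construct Design with Design-Specification Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for combinatorial DNA construct design: parts
    mapped onto annotated linear or circular source sequences, ordered
    combinatorial bins, a design-specification rule engine (WITH, NOTWITH,
    NOTMORETHAN), correct-by-construction validation diagnostics,
    rule-filtered enumeration and scar-less in-silico assembly of constructs,
    and direct-synthesis fragment cost accounting under firewall placements.
    Reads and writes GenBank flat files, versioned design documents (JSON and
    XML), Eugene-dialect rules files, and j5-style CSV part/order bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
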