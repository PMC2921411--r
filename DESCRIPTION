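Package: pyramabs
Title: Abstraction Pyramids from Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds multilevel abstraction pyramids from weighted, optionally
    directed networks. A bespoke node proximity combining direct link weights
    with probability-weighted two-step paths is computed at every level, weak
    links are pruned by z-score, a maximum-spanning-forest backbone guides a
    divisive partition of the network into modules, and modules are collapsed
    into supernodes to form the next level. The result exposes both vertical
    (inclusion) and horizontal (inter-module proximity) relationships.
    Includes a hierarchically nested random-network generator for validation,
    normalized-mutual-information scoring of recovered hierarchies against
    planted truth, and generic hypergeometric module-enrichment statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
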