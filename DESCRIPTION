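Package: cladistR
Title: Fitch Parsimony, Exact Tree Search and Jackknife Support for
    Morphological Character Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cladistic analysis of discrete morphological characters:
    a character-matrix container with NEXUS, TNT/Hennig86 and
    delimited-table input and output; Fitch (unordered) parsimony scoring
    with ensemble consistency and retention indices; exact search for all
    most parsimonious trees by branch and bound, seeded by stepwise
    addition and TBR branch swapping; character jackknife clade support
    with strict and majority-rule consensus; ancestral-state
    reconstruction with synapomorphy and homoplasy mapping; and
    simulation of character matrices with known generating trees.
    Ships the published character matrix for the darkling beetle genera
    Ectateus and Selinus and a one-call reproduction of that analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
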