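Package: nlrdiversity
Title: Diversity and Evolution Analysis of Plant NLR Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the diversity and evolution of plant
    nucleotide-binding leucine-rich repeat (NLR) resistance gene families.
    Classifies NLR proteins into TNL, CNL, RNL and NL architectures from
    domain annotation tables, screens candidate sets by phylogenetic
    placement among plant R proteins, calls gene-duplication and directed
    horizontal-gene-transfer events from species-labeled gene trees,
    detects recombination with a maximum chi-square sliding-window test
    and a multi-method consensus rule, summarises M7-versus-M8 positive
    selection tests, and correlates per-species gene counts with event
    frequencies. A birth-death-transfer gene-family simulator with domain
    gain/loss and planted recombinants provides ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
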