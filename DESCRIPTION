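Package: waspfam
Title: Domain-Architecture Classification and Phylogenetic Profiling of
    WASP-Family Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the short sequence elements that define the WASP family
    of ARP2/3 activators (WH2, central and acidic domains, CRIB, basic,
    poly-proline, serine-rich and charged low-complexity regions, coiled
    coils, and alignment-derived N-terminal family domains), resolves the
    detected elements into one ordered domain architecture per protein, and
    assigns each protein to the WASP, WAVE, WASH, WHAMM, WAWH or WAML
    subfamily with subtype, completeness class and pseudogene flag.
    Classifications are aggregated into species-by-family presence matrices
    and gene gain/loss events are reconstructed on a species tree by Dollo
    parsimony. A seeded synthetic-proteome generator with full ground truth
    provides a self-contained test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
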