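Package: mapkCascades
Title: Assembly of Plant MAPK Signaling Cascades from Interaction and
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing plant MAPKKK kinase families and
    assembling complete MAPKKK-MKK-MAPK signaling modules. Classifies
    kinases into the MEKK, Raf and ZIK subfamilies by catalytic-domain
    signature motifs, estimates Ka/Ks selection pressure on codon-aligned
    paralog pairs with the Nei-Gojobori counting method, z-scores tissue
    expression profiles, calls stress-induced genes from replicate
    qRT-PCR time courses via the Livak 2^-ddCt method with Student's
    t-tests, and enumerates tripartite cascade modules from yeast
    two-hybrid edge lists with shared stress-response annotation. Ships
    the published cotton (Gossypium hirsutum) interaction and induction
    data as fixtures and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
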