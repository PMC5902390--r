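Package: genuvar
Title: Structural Impact Assessment of Missense Variants at the Integrin alphaIIb Genu
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess missense variants in and around the genu
    ("knee") region of the platelet integrin alphaIIb subunit (ITGA2B).
    Maps variants between cDNA, HGVS protein and mature-protein numbering,
    computes Grantham physicochemical distances, scores positional
    conservation in multiple sequence alignments, and performs
    structure-based impact analysis on PDB coordinates: maximum-probability
    rotamer substitution, hydrogen-bond network differencing, van der Waals
    clash detection, disulfide-bridge and Ca2+ coordination-shell analysis,
    and side-chain orientation classification. Ships an embedded catalog of
    published Glanzmann thrombasthenia and platelet alloantigen variants in
    the aa471-769 region and a deterministic synthetic-structure generator
    so every detector is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
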