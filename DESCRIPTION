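Package: precisebe
Title: Design and Quantification Toolkit for High-Precision Cytosine Base Editors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with narrow-window cytosine base editors (BEs):
    IUPAC-aware PAM and protospacer discovery on both strands for a panel of
    Cas9 PAM variants, a knowledge base of editor activity windows and
    position preferences with a rule table that recommends editors from the
    distance of the target C to the PAM and its local sequence context, a
    scanner that classifies candidate pathogenic T-to-C (A-to-G) variants as
    precisely correctable or bystander-prone, per-position C-to-T conversion
    quantification from amplicon reads, substitution-spectrum tallies from
    variant calls, and seed-deterministic simulators that provide
    ground-truth-labelled reads, variant tables and call sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
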