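Package: pprkit
Title: Design and Structural Analysis of Pentatricopeptide Repeat RNA Binders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for programmable single-stranded RNA recognition by
    designer pentatricopeptide repeat (dPPR) proteins. Implements the
    bi-residue PPR code (repeat positions 5 and 35) as a configurable
    probabilistic table, assembles complete designer constructs for
    arbitrary ssRNA targets, detects tandem 35-residue PPR repeats in
    protein sequences and predicts their RNA targets as position
    probability matrices, scans transcripts for candidate binding sites,
    computes structural quantities of PPR-RNA complexes (iteratively
    pruned Kabsch superposition, superhelix axis/rise/twist/period,
    base-recognition hydrogen bonds and water bridges, Val2 sandwich and
    Lys13-phosphate contacts), and fits equilibrium dissociation
    constants from EMSA-style titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
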