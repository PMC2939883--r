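Package: cctpr
Title: Genome-Wide Screening for Carboxylate-Clamp TPR Co-Chaperone Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies carboxylate-clamp (CC) type tetratricopeptide-repeat
    (TPR) proteins, candidate co-chaperones of Hsp90/Hsp70, from protein
    sequences. Detects 34-residue TPR motifs with position-specific log-odds
    profiles, assembles them into three-motif domains (including a one-residue
    register-shift rescue), evaluates the five carboxylate-clamp consensus
    positions (K5/N9 in motif I, N6 in motif II, K2/R6 in motif III), types
    substitutions as conservative or radical by amino-acid class, performs a
    domain-architecture census, and builds neighbor-joining phylogenies with
    bootstrap supports. Ships curated motif alignments for the Arabidopsis
    thaliana and Oryza sativa CC-TPR families, and a synthetic-proteome
    generator with planted domains and clamp-broken decoys for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
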