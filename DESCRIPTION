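Package: groupcons
Title: Group-Specific Conservation Analysis of Protein Family Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for locating residue positions that are conserved within
    one subfamily of a protein family but not across the family as a whole.
    Provides per-column identity and residue-class similarity censuses of a
    multiple sequence alignment, a Kullback-Leibler group-entropy versus
    family-entropy scan over user-defined sequence groups, six column
    conservation estimators (Jensen-Shannon divergence, property entropy,
    von Neumann entropy, relative entropy, Shannon entropy, sum of pairs)
    consensus-intersected over background and substitution-matrix sweeps, a
    simplified evolutionary trace, neighbor-joining phylogenetics with
    column bootstrap and majority-rule consensus, scanning of PROSITE-style
    motif patterns, and a synthetic alignment generator with planted
    conserved sites for recovery benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
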