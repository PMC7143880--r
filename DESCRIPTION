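Package: bgcrep
Title: Comparative Analysis of PKS and NRPS Gene Cluster Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genome mining of polyketide synthase (PKS)
    and nonribosomal peptide synthetase (NRPS) biosynthetic gene clusters
    between closely related bacterial strains. Parses domain-organization
    strings of assembly-line synthases, predicts polyketide and peptide
    backbones by the colinearity rule, matches gene clusters between two
    strain inventories by module-architecture similarity, computes the rate
    of conserved clusters (RC, a Dice-type overlap percentage), evaluates
    16S rRNA gene pairwise identity, and relates RC to genome-based species
    delimitation measures (digital DNA-DNA hybridization, average nucleotide
    identity). Includes a synthetic inventory generator with known ground
    truth for validating conservation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
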