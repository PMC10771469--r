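Package: bindsurf
Title: Clustering Protein-Protein Interfaces into Binding Surfaces
Version: 1.0.0
Authors@R:
    person("bindsurf", "developers", email = "bindsurf@example.org",
           role = c("aut", "cre"))
Description: Quantifies the similarity between protein-protein interfaces
    mapped onto a common reference structure using a Gaussian-coupling
    inner product on C-alpha coordinates, clusters interfaces into binding
    surfaces by agglomerative hierarchical clustering, and derives
    downstream products: per-residue binding-surface probabilities,
    probability-encoded PDB files, a recognition entropy for pairs of
    interacting proteins, a rank-weighted docking-quality score, spatial
    clusters of residue lists, and combinatorial ambiguous-interaction
    restraints for information-driven docking. Includes a deterministic
    generator of synthetic C-alpha traces with planted binding surfaces so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
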