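# bindsurf

Proteins rarely use a single patch of their surface to interact: the
structural interactome records many slightly different interfaces for the
same protein, observed across crystal structures with different partners.
`bindsurf` takes a protein chain (Cα coordinates from a PDB file) plus a
list of curated interfaces (residue-number sets in a numbering consistent
with the structure, e.g. canonical sequence numbering) and answers: **how
many distinct binding surfaces does this protein have, where are they, and
how can they drive docking?**

It is aimed at structural bioinformaticians and integrative modellers who
already have interface lists (from data mining, experiments, or
predictors) and want an offline, reproducible clustering of those
interfaces into binding surfaces, together with docking-ready restraints.

## The model

An interface *I* is an indicator vector over the Cα atoms of the chain,
compared through a Gaussian kernel. With `J_ij = exp(−r_ij² / 4σ²)` the
coupling between atoms at distance `r_ij` (default σ = 1.9 Å, half the
consecutive Cα spacing):

- norm: `E(I) = Σ_{i,j ∈ I} J_ij`
- scalar product: `⟨φ_I, φ_J⟩ = Σ_{i∈I, j∈J} J_ij`
- distance: `D(I,J) = √(E(I) + E(J) − 2⟨φ_I, φ_J⟩)`
- angle: `cos θ = ⟨φ_I, φ_J⟩ / √(E(I)·E(J))`, similarity `sin θ ∈ [0, 1]`

`sin θ` is 0 for interfaces spanning the same surface region and 1 for
spatially disjoint ones, and unlike `D` it is insensitive to interface
size. Interfaces are clustered by average-linkage agglomerative clustering
of the `sin θ` matrix, cut at 0.866 (= sin 60°, inclusive). Each cluster is
a *binding surface*; residue *i* belongs to surface *K* with probability
`P_iK` = fraction of member interfaces containing *i*, written into the
B-factor column as `50·(1 + P)` for visualisation.

Downstream:

- recognition entropy `S = ln(N_rec × N_lig)`, the log of the number of
  binding-surface combinations of two partners (a proxy for docking
  ambiguity);
- docking-quality score `Q = Σ_m Σ_t Q_mt / t` over the top-(1, 5, 10, 50,
  100) array, `Q_mt ∈ {0..3}`;
- spatial clustering of flat residue lists (Cα–Cα distances, average
  linkage, 15 Å cutoff);
- one ambiguous-restraint set per surface combination, keeping residues
  with `P ≥ 0.3`.

## Worked example

Everything is testable offline through the built-in generator of helical
Cα traces with planted binding surfaces:

```r
library(bindsurf)

sc  <- generate_scenario(k = 3, patch_size = 10, replicates = 5,
                         dropout = 0.2, seed = 42)
sim <- similarity_matrix(sc$interfaces, sc$structure)
res <- cluster_interfaces(sim, sc$interfaces)
res
#> <clustering_result> 15 interface(s) -> 3 binding surface(s) [average linkage, threshold 0.866]
#>   sizes: 5, 5, 5

max(sim$values[1:5, 1:5])    # within-surface similarity
#> [1] 0.402
min(sim$values[1:5, 6:10])   # between-surface similarity
#> [1] 1

head(sort(res$profiles[[1]]$probabilities, decreasing = TRUE))
#>  11  14  16  19  20  12
#> 1.0 1.0 1.0 1.0 1.0 0.8

recognition_entropy(3, 1)    # 3 surfaces here x 1 on a partner
#> [1] 1.098612
```

The 15 noisy interface replicates collapse into exactly the 3 planted
surfaces: replicates of one patch stay well below the 0.866 cut
(sin θ ≤ 0.40) while patches on different parts of the helix are
orthogonal (sin θ ≈ 1). Residues seen in all 5 replicates of surface 1
get `P = 1.0` (B-factor 100.00 in the probability PDB); residue 12,
dropped once, gets `P = 0.8` (B-factor 90.00).

The same pipeline runs from the command line:

```sh
inst/bin/bindsurf fixtures --k 3 --out fixture
inst/bin/bindsurf cluster --pdb fixture/fixture.pdb \
    --interfaces fixture/interfaces.json --out run
inst/bin/bindsurf metrics --n-rec 13 --n-lig 4
# S_recognition  3.95
```

Subcommands: `cluster`, `resclust`, `restraints`, `localise`, `metrics`,
`fixtures`. Key flags mirror the tunables: `--sigma`, `--linkage`,
`--threshold`, `--int-cov-cutoff`, `--p-thr`, `--chain-to-use`,
`--pdb-to-use`.

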