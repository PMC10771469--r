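---
title: "Clustering protein interfaces into binding surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering protein interfaces into binding surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindsurf)
```

## The problem

A protein observed in many complexes exposes many *interfaces* — residue
sets in contact with a partner — that are noisy observations of a smaller
number of *binding surfaces*. `bindsurf` groups interfaces mapped onto one
reference chain into those surfaces and derives products useful for
integrative docking. This vignette explains the model, its assumptions,
the tunable parameters, what the synthetic test world does and does not
establish, and the design choices made where the design was genuinely
open.

## Model and assumptions

Each interface is an indicator function over the chain's Cα atoms,
embedded in a function space via a Gaussian kernel: the coupling between
atoms $i, j$ at distance $r_{ij}$ is $J_{ij} = e^{-r_{ij}^2 / 4\sigma^2}$.
Interface norms $E(I)$, scalar products
$\langle\phi_I, \phi_J\rangle$ (double sums of couplings over residue
pairs, diagonal included), distances
$D = \sqrt{E(I) + E(J) - 2\langle\phi_I,\phi_J\rangle}$ and angles
$\cos\theta = \langle\phi_I,\phi_J\rangle / \sqrt{E(I)E(J)}$ follow.
The working similarity is $\sin\theta$ because, unlike $D$, it does not
grow with interface size: two size-mismatched interfaces covering the same
patch still score near 0.

Assumptions worth spelling out:

- **Cα-only geometry.** Side chains are ignored; an interface is where its
  backbone sits, at the resolution set by $\sigma$.
- **Consistent numbering.** Interface residue numbers must already match
  the structure's numbering (canonical/sequence numbering in practice).
  The package deliberately performs no renumbering and no network lookups;
  residues with insertion codes are rejected so keys stay integral.
- **Single chain, first model.** Multi-chain files need an explicit chain
  selection; only the first model of multi-model files is read; the first
  alternate location wins.
- **Diagonal terms included.** The double sums include $i = j$; this makes
  $E$ of a single-residue interface exactly 1 and $\cos\theta(I,I)$
  exactly 1, which the identities in the test-suite rely on.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `sigma` | 1.9 | Å | Gaussian width; half the consecutive Cα spacing (3.8 Å), so neighbouring residues couple strongly ($e^{-1}$) and residues ≥ 4σ apart are effectively decoupled ($e^{-4}$). |
| `threshold` | 0.866 | — | dendrogram cut on $\sin\theta$; equals $\sin 60^\circ$, i.e. interfaces closer than 60° in the Hilbert-space angle end up on one surface. |
| `linkage` | average | — | merge rule; single/complete/ward.D2 are exposed but only average carries the defaults' semantics. |
| `int_cov_cutoff` | 0.7 | fraction | an interface is retained when at least 70% of its residues exist in the structure (inclusive at the boundary); retained interfaces are projected onto the structure. |
| `p_thr` | 0.3 | fraction | minimum per-residue surface probability for a residue to enter a restraint set (inclusive, so 1.0 selects unanimous residues). |
| resclust `cutoff` | 15 | Å | Cα–Cα distance cut for spatial clustering of flat residue lists. |

Scaling note: the algebra depends only on $r_{ij}/\sigma$, so doubling all
coordinates and $\sigma$ changes nothing — $\sigma$ is genuinely the only
length scale of the similarity model.

## Numerical choices

- $\cos\theta$ is clipped into $[0, 1]$ before the square root: all
  couplings are positive so $\cos\theta \ge 0$ analytically, but floating
  error can push it marginally above 1, which would otherwise make
  $\sqrt{1 - \cos^2}$ NaN. Likewise the radicand of $D$ is clamped at 0.
- The coupling matrix is dense; no distance truncation is applied. Single
  chains have at most a few thousand residues, well within memory, and a
  cutoff would break the exact identities used by the oracle tests.
- **Inclusive cuts.** Whether a merge at exactly the threshold is accepted
  is not dictated by the method itself; this package accepts it
  (cophenetic distance ≤ threshold), matching the common distance-criterion
  convention, and the same convention is used for the coverage filter, the
  15 Å residue clustering, and the `p_thr` filter (≥). Each boundary is
  pinned by a test.
- **Tie-breaks.** Clustering is delegated to `stats::hclust`, whose
  internal merge order for exactly tied linkage values is not configurable.
  Exact ties essentially arise only from duplicated interfaces (distance
  0), where any merge order yields the same partition; correctness tests
  therefore compare partitions, not dendrograms.
- Cluster ids are assigned 1..k by decreasing member count, ties by the
  earliest member in input order, so labels are deterministic and stable
  under relabelling of the input.
- A single interface short-circuits to one singleton cluster without
  invoking the clustering engine (a 1×1 "distance matrix" is not a
  meaningful hclust input).

## Open design points and how they were resolved

- **Coverage accounting.** The 70% test counts the interface's *full*
  residue list in the denominator, before projection onto the chain. This
  reading makes the filter independent of the order of projection and
  filtering, and keeps `filter_interfaces` idempotent.
- **Reference-structure selection.** Among candidate structures the one
  retaining the most interfaces wins; ties go to the earliest candidate,
  assuming the caller has pre-ranked candidates (e.g. by coverage and
  resolution).
- **Docking-quality weights.** In $Q = \sum_m \sum_t Q_{mt}/t$ the weight
  is the *rank index* of the top-$(1, 5, 10, 50, 100)$ array ($t = 1..5$),
  not the top-$N$ value; the per-method maximum is therefore
  $3 H_5 = 137/20$. The "best model so far" semantics is enforced as an
  input invariant — qualities must be non-decreasing in $t$ — rather than
  recomputed from model lists the package never sees.
- **Restraint dialect.** One ambiguous distance statement per receptor
  residue against the full ligand residue list (active–active ambiguity
  only, no passive residues), with a configurable 2.0 Å effective
  distance. The docking engine's exact dialect requirements go beyond
  what the method defines, so the writer keeps the statement minimal and
  deterministic (byte-identical regeneration).
- **Partner-level counting.** Annotation aggregation counts *distinct
  partners* per cluster, not interfaces: a partner contributing several
  interfaces to one surface counts once. Partners missing from the
  user-supplied table are reported under `unannotated` with a warning
  rather than dropped, so per-cluster counts always add up.

## The synthetic world

`generate_scenario()` builds an ideal α-helical Cα trace — rise 1.5 Å and
100° per residue, radius chosen so consecutive Cα atoms are exactly 3.8 Å
apart — and plants `k` sequence-contiguous patches separated by a
sequence gap (default 10 residues ≈ 16.5 Å spatially, beyond the 4σ
coupling range). Each surface is observed through `replicates` interfaces
with per-residue dropout, emulating incomplete interface observations
mined from different crystal structures. Defaults used by the recovery
tests: 3 surfaces × 10 residues × 5 replicates, dropout 0.2.

What the generator emulates: replicate interfaces that differ in residue
composition but share a location; spatially disjoint surfaces; optional
coordinate jitter. What it does not: realistic tertiary folds (surfaces
here separate cleanly along the helix axis), partially overlapping
surfaces, interfaces spanning discontinuous sequence segments, or
non-uniform residue observation bias. A green recovery test therefore
establishes that the pipeline separates well-separated surfaces under
moderate dropout — not that the 0.866 default optimally resolves the
truly ambiguous, partially overlapping interfaces of real proteins.

```{r recovery}
sc  <- generate_scenario(k = 3, patch_size = 10, replicates = 5,
                         dropout = 0.2, seed = 42)
res <- cluster_interfaces(similarity_matrix(sc$interfaces, sc$structure),
                          sc$interfaces)
res
table(res$assignment, sc$truth[names(res$assignment)])
```

## Known limitations

- No structure retrieval, renumbering, or sequence mapping: inputs must
  arrive numbering-consistent.
- Interfaces are residue sets on *one* chain; inter-chain interfaces and
  all-atom couplings are out of scope.
- `sin θ` saturates at 1 for all well-separated surface pairs, so the
  dendrogram carries no information about *how* far apart distinct
  surfaces are — only that they are distinct.
- Average linkage on a saturated similarity matrix can, in principle,
  chain intermediate interfaces into bridged clusters; the threshold
  mitigates but does not eliminate this on heavily overlapping real data.
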