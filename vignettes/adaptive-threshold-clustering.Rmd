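---
title: "Adaptive-threshold sequence clustering: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-threshold sequence clustering: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afclust)
```

## The model

`afclust` treats sequence clustering as iterative community detection on a
complete weighted graph. Its central assumption is that homologous
sequences have substantially higher pairwise similarity with each other
than with non-homologous sequences, and that a single global identity
threshold cannot serve every cluster at once.

**Distances.** Pairwise similarity is alignment-free: each sequence is
summarized by the `s` smallest 64-bit hash values over its distinct
k-mers (a bottom-`s` MinHash sketch), the Jaccard index `j` of two k-mer
sets is estimated from the `s` smallest values of the union of two
sketches, and the Mash distance is

$$d = -\frac{1}{k}\,\ln\frac{2j}{1+j}, \qquad d \in [0, 1],$$

with `j = 0` mapped to `d = 1`. Similarity is `w = 1 − d`. For nucleotides
a k-mer and its reverse complement hash identically (the
lexicographically smaller strand is hashed), so distances are
strand-invariant. K-mers containing characters outside the strict
alphabet (`N`, `X`, …) are skipped entirely rather than randomized, so
sketches are deterministic.

**Raw clusters.** An undirected complete graph `G = (V, E, W)` has one
vertex per sequence; `w_ij` is the edge weight and the diagonal `w_ii`
stores a *vertex weight* (the mean internal similarity of the cluster a
vertex represents; 1 for a single sequence). Vertex weights are not
self-loops and never enter the quality function. At resolution
`γ ∈ [0, 1]`, raw clusters maximize the Constant Potts Model quality

$$q = \sum_{i<j} (w_{ij} - \gamma)\,\delta(\sigma_i, \sigma_j).$$

The all-singleton partition scores 0, so the optimum is never negative,
and every member of a non-singleton raw cluster must exceed mean
intra-cluster similarity `γ` — `γ` is a floor on cluster cohesion. Low
`γ` values, however, bias CPM toward larger clusters over higher edge
weights, which is why the algorithm approaches its target resolution
gradually from above rather than jumping to it.

**Binning.** From the second iteration on, each raw cluster is re-examined
with an adaptive rule. Vertices enter a list `J` by descending
intra-cluster edge weight (the endpoint representing more underlying
sequences first). The first vertex seeds a bin; each later vertex `v_t`
may join a bin `B` only when

$$I_{bin}(B) - I(B, v_t) \;<\; I(B, v_t) - \gamma_{low},$$

where `I_bin` is the mean similarity over all primitive sequence pairs
inside `B` and `I` is the mean similarity between `v_t`'s and `B`'s
primitive sequences. The left side measures cluster separation, the right
side is a cut-off derived from the bin itself — every bin has its own
effective threshold above the floor `γ_low`. The rule is applied through
the score `Q = 2I − I_bin − γ_low`; `v_t` joins the bin with the highest
strictly positive `Q` or seeds a new bin. Note a structural consequence:
against a bin holding a single sequence (`I_bin = 1`), admission requires
similarity above `(1 + γ_low)/2`, so clusters only nucleate on pairs
whose similarity clears that bound.

**Contraction.** Every bin becomes one vertex. All weights of the
contracted graph are exact arithmetic means of primitive-pair
similarities (the ρ-weighted forms of the binning equations then coincide
with primitive averages, which is how the package computes them). Bins
split from one raw cluster are *forbidden pairs*: their edges carry the
sentinel weight `−|V'|²`, which makes any partition co-clustering them
strictly worse than splitting, and the status is hereditary across later
contractions. The sentinel never contaminates averages because averages
are always recomputed from the primitive matrix.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 17 nt / 9 aa | k-mer length; 13 recommended for short nucleotide sequences |
| `sketch_size` | 2000 | bottom-s sketch capacity |
| `hash_seed` | 42 | fixed hash seed; part of the sketch definition |
| `gamma_high` | 0.95 | starting resolution; should stay near 1 so the first raw clusters resist size bias |
| `gamma_low` | 0.75 | soft cut-off floor; suggested range 0.7–0.8 |
| `delta` | 0.025 | resolution step; larger steps re-admit size bias |
| `precluster_limit` | 20000 | input size above which greedy pre-clustering partitions the input |
| `seed` | 0 | seed for the community-detection starts |

`γ_low` is a *soft* cut-off: the actual cut-off of each cluster is
`I(B, v_t) − γ_low`, which adapts to the bin; results are therefore far
less sensitive to `γ_low` than greedy clustering is to a hard identity
threshold, and the end-to-end tests assert identical clusterings across
`γ_low ∈ {0.7, 0.75, 0.8}` on well-separated families.

## Numerical choices

- The `γ` schedule is computed on an exact decimal grid (scaled
  integers), because accumulating `γ − Δ` in binary floating point can
  corrupt the loop bound `γ > γ_low − Δ`.
- Contracted weight matrices are symmetrized exactly after the block
  averaging; the two triangles are sums of the same terms in different
  orders and can differ by ~1e−16, which strict symmetry checks reject.
- Hash values are truncated to 53 bits so they are exactly representable
  as R doubles; collisions in a 53-bit space are negligible at sketch
  scale.
- Tie-breaks are all deterministic: equal edge weights sort by smaller
  vertex-index pair; equal ρ appends the smaller index first; equal
  maximal `Q` joins the earliest-created bin; equal center scores pick
  the smallest id. `Q` is compared with a strict `> 0`; an exact zero
  seeds a new bin.
- Raw-cluster detection runs a small fixed number of seeded Leiden starts
  and keeps the best score, then applies deterministic single-vertex
  local moves until no move improves `q`. The contract is `q ≥ 0`, local
  optimality, forbidden-pair exclusion and seeded determinism — global
  optimality is not promised (matching the heuristic nature of community
  detection), though on random complete graphs with ≤ 8 vertices the
  suite verifies the brute-force optimum is found in ≥ 95% of instances.
- Degenerate inputs: a single sequence returns one singleton without
  building a graph; sequences shorter than `k` are excluded with a
  warning naming them; an input left empty after filtering is an error.

## Cluster evaluation

For every non-singleton cluster the representative center is the member
with the largest sum of intra-cluster similarities among members whose
length lies within `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` (linear-interpolation
quartiles); if none qualifies, or the cluster has exactly two members,
the longest sequence is chosen. Identity between the center and each
member is computed from a global alignment with free end gaps as matched
columns over alignment columns, terminal-gap columns excluded. The
alignment scoring (+1/−1 with linear gap 2 for nucleotides; BLOSUM62
with gap open 11 / extend 1 for proteins) is a documented package
convention; because identity is defined purely by matched columns over
retained columns, scoring choices affect the result only through the
alignment path.

For validation against known classes the package implements NMI and
purity exactly from their definitions (natural logarithm; NMI of two
single-group partitions is defined as 1) and the mean silhouette with
singleton members contributing width 0 — both conventions the field
commonly uses where the definitions are silent.

## The synthetic generator

`generate_families()` produces labelled homologous families: one random
ancestor per family, members derived by i.i.d. per-site substitutions and
geometric indels (mean length 2). `divergence` is the expected per-site
divergence **between two members** — each member mutates at
`divergence/2` from the ancestor — so mean within-family identity is
about `1 − divergence`; this pairwise parameterization is what the
recovery tests measure with `pairwise_identity()`. Ancestors are drawn
independently, so between-family similarity sits at the random
background (Mash similarity ≈ 0).

What the generator does *not* emulate: compositional bias, repeats and
low-complexity regions, partially overlapping sequences (the known
failure mode of Mash distances, which underestimates distances between
sequences sharing only a segment), length heterogeneity within a family
beyond indels, and gradual similarity between families. Passing the
end-to-end tests therefore shows the algorithm recovers well-separated
homologous families and honours its own guarantees; it does not certify
behaviour on data with heavy partial overlaps, for which the evaluation
report (low minimum identities) is the intended diagnostic.

The test and acceptance runs use 20 families of 5–30 members, ancestor
lengths 600–1200 and pairwise divergence 0.05 — family structure at the
scale of a typical gene-family dataset, chosen to exercise all algorithm
stages (singleton start, gradual merging, binning, contraction) in a
suite that completes in minutes on a laptop.

## Known limitations

- Mash distances underestimate divergence for partially overlapping
  sequences; such pairs can be clustered together and surface only in
  the evaluation report as low minimum identity.
- The graph per partition is dense (O(N²) memory); inputs beyond the
  pre-cluster limit are handled by greedy sketch-based partitioning at
  `γ_low`, which is exact only when cross-partition similarities are
  genuinely below `γ_low`.
- The method targets groups of complete homologous sequences; it is not
  an OTU clusterer with a fixed 97% threshold, nor a read clusterer.
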