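---
title: "Fusing multi-atlas cognitive networks by graph discriminability"
author: "netfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-atlas cognitive networks by graph discriminability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain atlases disagree about which regions constitute a given cognitive
network. The fronto-parietal network (FPN), for example, is delineated
with 10 regions by an AAL-based definition, 21 ROIs by Dosenbach-160,
25 by Power-264, and — under the name "executive control network" — 24
regions by Willard-499. Any analysis committed to a single atlas
therefore sees only one version of the network. netfuse implements a
fusion procedure that (i) synthesizes all atlas instances of one network
into a *combined* network, (ii) selects the single instance whose graph
properties best discriminate cognitive conditions as the *main* network,
and (iii) greedily absorbs the most discriminative remaining ROIs to
form a *fused* network.

## The model and procedure

**Combined network.** Instances are harmonized to a common anatomical
boundary by lobe clipping (the shipped default keeps `frontal` and
`parietal`, the FPN boundary, and is fully configurable), then
concatenated. Two deliberate identity rules apply: within one instance
no two ROIs may share MNI coordinates, while across instances
coordinate duplicates are *retained* as distinct members — ROI identity
is the pair (source atlas, roi id), never the coordinates. Combination
is therefore always size-additive.

**Connectivity stack.** For each condition $c$ and subject $s$ the ROI
time series are correlated (Pearson product-moment; two-sided p-values
from the $t$ distribution on $t-2$ df), giving a 4-D array indexed
(condition, subject, ROI, ROI). Each slice is thresholded into a binary
graph: Benjamini–Hochberg FDR control at rate $q$ (default 0.05) over
the slice's node pairs, keeping positive edges only by default
(`mode = "absolute"` keeps both signs).

**Discriminability.** A candidate ROI subset $S$ is scored by computing
a graph property of $S$ on every slice's graph — an index matrix of
shape conditions × subjects — and testing its rows. With two conditions
a two-sided t test is used; with more, one-way ANOVA. Degree centrality
is the default property; clustering coefficient and global (inverse
shortest path) efficiency are available behind the same interface.

**Selection and fusion.** Every instance is scored as a candidate; the
minimum p-value wins (first occurrence on exact ties). The remaining
ROIs are ranked ascending by the discriminability of their *nodal*
degree centrality within the full combined-network graph, again with
stable ties, and degenerate ROIs (property constant across all
subjects and conditions) sink to the end at p = 1. Fusion then
evaluates the main network plus every prefix of that priority list —
including the empty prefix — and absorbs the prefix with the minimum
p-value. Because prefix length 0 participates in the search, the fused
network can never score worse than the main network alone, and the
whole search is deterministic.

## Design choices at genuinely open points

* **"Optimal performance" = minimum p-value.** The selection rule is
  stated as an inequality on $P(\cdot)$ that reads as "greater or
  equal", but a p-value measures discriminability inversely, and the
  reported orderings are ascending in p. netfuse uses argmin
  throughout.
* **Candidate scope.** For a multi-ROI candidate the degree property is
  computed on the subgraph *induced* by the candidate (normalized by
  $|S|-1$): the score of a candidate should not depend on ROIs outside
  it. For a single ROI the only meaningful reading is its degree within
  the full combined-network graph (normalized by $|CCN|-1$). Both are
  exposed via `graphProperty(..., scope =)`.
* **Paired t test by default.** The intended design is within-subject —
  the same subjects perform every condition — so pairing is implied;
  `paired = FALSE` switches to the pooled two-sample test. The χ²
  variant sometimes mentioned alongside the t test is not implemented:
  the property values are continuous.
* **Raw p-values for ranking.** Candidate and nodal p-values are used
  exactly as computed, with no multiple-testing correction across
  candidates — the ranking, not the inference, is what the algorithm
  consumes.
* **FDR scope.** BH runs per connectivity matrix (per slice), without a
  Fisher z transform of the correlations beforehand. Edge selection is
  a per-graph construction step, not a pooled inference.
* **Editorial exclusions are not hard-coded.** The small manually
  defined atlas (9 ROIs, 2 in the insula) clips to 7 frontal/parietal
  ROIs like any other instance; whether it participates in a
  combination is the caller's decision. The shipped clipped fixture set
  excludes it, mirroring common practice of dropping sparsely validated
  atlases.
* **Graph metrics are computed directly from the adjacency matrix**
  (degree arithmetic; triangle counts via $\mathrm{diag}(A^3)$; geodesics by
  breadth-first expansion of the reachability matrix). These
  definitions are elementary, and the direct forms keep the per-slice,
  per-candidate inner loops cheap; igraph serves as an independent
  cross-check in the test suite rather than as the implementation.

## The synthetic generator

Real task-fMRI recordings are not bundled, so the planted-subnetwork
generator stands in for them and defines the study conditions end to
end. `plantedDesign()` defaults mirror the emulated study: 2 conditions
× 21 subjects × 72 ROIs (instances 10/21/24/17; 47 frontal, 25 parietal),
t = 180 time points. A known planted ROI set — by default the whole
second instance plus the first ROI of each other instance, so the
signal is anchored in one instance but spills into supplementary
candidates — carries the condition effect:

| parameter | default | meaning |
|---|---|---|
| `baseCorr` | 0.30 | planted-block correlation in the unaffected condition; a typical within-network functional-connectivity level, high enough that thresholded graphs are non-degenerate |
| `effect` | 0.40 | added planted-block correlation in condition 1 (0.7 vs 0.3 is a strong, but plausible, task modulation) |
| `subjectSd` | 0.05 | SD of the per-subject correlation jitter, shared across that subject's conditions (a within-subject design) |
| off-block | `baseCorr/2` | background correlation between all other pairs, condition-independent |

Targets are checked for positive semidefiniteness up front (generation
aborts with the offending eigenvalue if the requested blocks are
infeasible); jittered per-subject targets are projected to the nearest
PSD correlation matrix by eigenvalue clipping before Cholesky sampling.
Everything is reproducible from the design seed.

The generator emulates condition-dependent correlation structure,
between-subject variability, and stationary Gaussian noise. It does
*not* model hemodynamics, temporal autocorrelation, motion or other
artifacts, or spatial smoothness — so passing tests demonstrate the
correctness and calibration of the pipeline's statistics on its stated
model, not robustness to fMRI acquisition physics.

## Problem sizes used by the tests

The test and calibration suites run the generator at a reduced scale
chosen to exercise every stage quickly: 2 conditions × 8 subjects ×
24 ROIs (instances 3/7/8/6), t = 60. At this scale the suite verifies,
among others: exact agreement of the greedy fusion with exhaustive
prefix re-evaluation on 50 random stacks; agreement of BH-FDR and of
all three graph metrics with brute-force definitions (exhaustively over
every graph with up to 6 nodes); a null rejection rate of the candidate
score within the binomial 99% interval around 0.05 over 1000
no-effect replicates; and, at the strong-effect defaults, recovery of
the planted instance as main with high fused recall over 100
replicates. `scripts/acceptance.R` recomputes these quantities from
scratch.

## Numerical and degenerate-input conventions

* Zero-variance time series produce r = 0, p = 1 edges with a warning
  instead of aborting a group run.
* `discriminability` returns p = 1 (with a warning) when every
  condition row is constant; constant non-zero paired differences
  return the limiting p = 0.
* Exact ties in instance scores or prefix p-values resolve to the first
  occurrence, making runs order-deterministic.
* Correlations are clipped to [-1, 1] before p-value computation;
  Cholesky factorization adds a 1e-8 ridge after PSD projection.

## Limitations

The package assumes preprocessed, MNI-normalized inputs (ROI tables or
ROI time series; optionally spherical extraction from 4-D NIfTI
volumes). It performs no preprocessing, no weighted-graph metrics, no
community detection, and no repeated-measures ANOVA; with more than two
conditions the dispatcher uses ordinary one-way ANOVA. The prefix
search considers only prefixes of the priority list, not general ROI
subsets — that restriction is the algorithm, not a shortcut. External
rankings (e.g. from tree-ensemble feature importances) can be plugged
into `fuseNetworks(suppOrder =)` to drive the same search.
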