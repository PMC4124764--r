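---
title: "Scoring miRNA-disease associations by bidirectional network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA-disease associations by bidirectional network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdnet)
```

## The model

A miRNA is linked to a disease when the genes it represses are functionally
close to the genes that cause the disease. `mirdnet` operationalises
"functionally close" as proximity on a protein-protein interaction (PPI)
network, measured in both directions:

1. Propagate the disease genes over the network with a random walk with
   restart (RWR) and ask whether the miRNA's targets concentrate at the top
   of the resulting gene ranking (score ES1).
2. Propagate the targets and ask the same of the disease genes (ES2).
3. Combine: ES = beta * ES1 + (1 - beta) * ES2.

The assumptions this encodes are worth stating. First, the PPI network is
treated as an undirected, unweighted, reasonably complete map of functional
relatedness; edges are taken at face value, and analyses run on the largest
connected component so every gene is reachable. Second, proximity is
symmetric in spirit but not in computation - the two RWR runs give genuinely
different rankings, which is why both directions are scored and averaged.
Third, set sizes are informative but must not dominate: the running-sum
increments normalise by set size, and significance is judged against a null
that preserves each gene's degree exactly.

### The random walk

The walker's stationary distribution solves
`p = (1 - alpha) * W %*% p + alpha * p0`, with `W` the column-normalized
adjacency and `p0` uniform over the seed set. We iterate to the fixed point
(power iteration) rather than solving the linear system, which keeps memory
proportional to the edge count; a dense direct solve exists in the test
suite as the independent oracle, and the two agree to 1e-8 on seeded random
graphs across alpha in {0.1, 0.5, 0.9}.

Numerical choices:

* **Normalization.** Column normalization (each neighbour of a degree-d gene
  receives 1/d of its outflow) rather than the symmetric
  `D^-1/2 A D^-1/2` variant; the choice matters only through the ranking it
  induces, and the column form is the standard random-walk reading.
* **Convergence.** L1 change below `tol` (1e-10 for user-facing ranking;
  1e-8 inside the all-pairs scan, where only the rank order matters since
  the contraction factor `1 - alpha` makes late iterations shuffle
  probabilities far below rank resolution). Non-convergence inside
  `max_iter` warns and returns the current iterate.
* **Ties.** Structurally equivalent genes tie exactly; ranks break ties by
  ascending gene identifier so that every downstream enrichment score is
  reproducible across platforms.
* **Disconnected inputs.** Randomized networks need not be connected. Genes
  in components without a seed receive probability exactly 0 (they get no
  restart mass and no flow), which is the correct limit, and the total
  probability still sums to 1.
* **Seed genes stay in the ranking.** A seed that is also a query gene
  counts like any other gene; nothing in the formulation excludes it.

### The enrichment score

Walking a ranking of `N` genes from the top, the running sum rises by
`(N - n)/n` at each of the `n` query genes and falls by `n/(N - n)`
otherwise; the score is the maximum prefix value. Two properties follow
directly and are enforced as test invariants: the score can never exceed
`N - n` (all hits first), and the final prefix always equals `N - 2n`. Note
this is *not* the zero-sum GSEA normalization - the increments are taken
literally as stated, so the running sum ends at `N - 2n`, not 0. A
`--gsea-normalized` variant was deliberately not added.

One degenerate case needs a policy: when every prefix is negative (possible
only when the query set covers more than half the ranking with a miss at the
top), the maximum is negative. We return it with a warning rather than
clamping to zero, since the definition is a maximum with no clamp; clamping
would silently break the permutation null's exchangeability.

Query genes absent from the ranking are dropped before scanning, consistent
with the annotation filter; a query entirely outside the ranking, or equal
to the whole ranking, is an error.

### Significance

The null model randomizes the *network*, not the gene sets: each of
`n_null` networks is a degree-preserving Maslov-Sneppen randomization
(double-edge swaps rejecting self-loops and duplicates; 10 attempted swaps
per edge by default, a standard mixing length, configurable since the
original procedure's mixing length is not stated). The same seed sets are
rescored on every member and `p = k / n_null` with `k` the count of null
scores greater than or equal to the observed one. Ties count as extreme, `p`
can be exactly 0, and an optional `(k + 1)/(n + 1)` pseudocount mode exists
but is off by default because the plain fraction is the stated definition.

Two engineering decisions keep this tractable. One ensemble is shared by all
pairs (member `i` is regenerated deterministically from `seed + i`, so
nothing needs to be stored), and per-network rankings are computed once per
*seed set*, not per pair: the cost is `n_null * (n_diseases + n_mirnas)`
propagations instead of `2 * n_null * n_pairs`. Connectivity is not enforced
on ensemble members - degree preservation is the stated constraint, and the
RWR handles disconnected members as described above.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `alpha` | 0.7 | Restart probability; ranking quality is flat over 0.5-0.9, so the default sits mid-plateau. |
| `beta` | 0.5 | Weight of ES1 vs ES2; 0.5 treats both propagation directions equally, and performance is insensitive across 0.1-0.9. |
| `delta` | 0.05 | p-value threshold for a bipartite edge, strict (`p < delta`); changing it changes how many associations survive, never their within-disease order. |
| `n_null` | 1000 | Random networks in the null; tests and desk-scale runs use 50-200 (p-resolution 1/n_null). |
| `swaps_per_edge` | 10 | Edge-switch attempts per edge per random network. |
| `min_databases` | 3 | Distinct target databases that must support a (miRNA, gene) pair. |
| `min_genes` | 5 (miRNAs) / 0 (diseases) | Strict lower bound on in-network set size after annotation. The miRNA-side rule is stated ("more than five"); the disease-side rule is not, so diseases are kept by default. |

## The bipartite analyses

**BD and BH.** The published formulas for the class-modularity pair live in
an unavailable supplement, so the package implements a documented
reconstruction: with `s(di, dj)` the number of miRNAs linked to both
diseases, BD is the mean of `s` over within-class pairs and BH the mean over
(in-class, out-of-class) pairs, each divided by the mean over all disease
pairs. This satisfies every interpretive property the measures are used for:
BD > 1 with BH < 1 flags clear clustering, BD > BH a clustering tendency,
random class labels give BD near 1 in expectation (verified by a
permutation test), and the measures are invariant to miRNA relabeling. It
should not be quoted as the original definition.

**Clustering.** Two-way hierarchical clustering of the *binary* incidence
matrix (an edge either survived the threshold or did not; the p-values are
not reused as weights) with city-block distance and complete linkage.
Module extraction, done visually in the original workflow, is automated
here: cut both dendrograms at a chosen number of clusters and report every
(disease-cluster, miRNA-cluster) block whose edge density reaches
`min_density` (default 0.8). `hclust` merge order is deterministic for a
fixed input order, and the incidence matrix rows/columns are always sorted,
so results are reproducible.

**Evaluation.** ROC curves sweep the decision threshold over all distinct
p-values; lower p is a stronger prediction. The original TN/FN prose is
internally inconsistent (it assigns both TN and FP to `p <= delta`), so the
standard confusion-matrix semantics are used - negative calls at
`p > delta` - which is what the stated sensitivity and specificity formulas
force. AUC is trapezoidal and equals the Mann-Whitney concordant-pair
fraction (ties at half weight); the identity is a test oracle, not an
implementation shortcut. The hypergeometric baseline scores a pair by
target/disease-gene overlap alone (`stats::phyper`, upper tail) and exists
for comparison: proximity-without-overlap signal is exactly what it cannot
see.

## The synthetic world

`simulate_mirna_disease()` states the world the tests run in: a
preferential-attachment network (hub-dominated degrees like a real PPI map;
`attachment = 4` gives mean degree near 8, matching the real network's
~8), disease modules grown as seeded network neighbourhoods
(`module_cohesion` = probability each added gene is a neighbour of the
module so far), and miRNA target sets in which `signal_fraction` of targets
are drawn from the module's immediate neighbourhood *excluding the module
itself* - the planted signal is proximity, never overlap, which is the
method's distinctive claim and keeps the hypergeometric baseline blind to
it. Half the miRNAs are uniform-target negatives; classes share regulator
pools through `class_overlap`. Defaults (10-40 sets of 8-25 genes on
300-800 genes) mirror the real inputs' set-size scale, chosen once at desk
scale.

What a green test does establish: the solver matches closed forms; the
statistic matches brute-force evaluation; the null is calibrated (uniform
p-values, nominal false-positive rate) when no signal is planted; planted
proximity signal is recovered (AUC >= 0.8) and beats the overlap baseline;
planted class structure yields BD > 1 > BH behaviour; planted blocks are
recovered by the clustering. What it does not establish: performance on real
curated inputs - the generator has no study bias, no false edges, no
correlated annotation errors, and its degree distribution only approximates
a real interactome's - nor any multiple-testing control across pairs
(thresholding raw p-values is the stated procedure and is preserved; treat
the network's edge count, not any single edge, as the calibrated object).

## Known limitations

* Gene identifiers are opaque strings; no identifier mapping or validation
  is attempted, so the caller must pre-harmonise network and set
  identifiers.
* The permutation p-value's resolution is 1/`n_null`; with the default
  threshold 0.05 and `n_null` = 100, only k <= 4 survives.
* Edge switching may disconnect a randomized network; this is handled, not
  prevented, since only degrees are constrained.
* BD/BH is a reconstruction (above); absolute values should be compared
  within this package only, though their qualitative reading is stable.
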