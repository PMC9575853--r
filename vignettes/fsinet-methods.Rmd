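---
title: "Methods: similarity integration and network propagation for DTI prediction"
author: "fsinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity integration and network propagation for DTI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsinet)
```

# The model

Drug–target interaction (DTI) prediction is cast as link prediction on a
three-layer heterogeneous network: an $m \times m$ drug–drug similarity
matrix $W_{dd}$, an $n \times n$ target–target similarity matrix $W_{tt}$,
and the binary $m \times n$ matrix $W^0$ of known interactions. Scores are
obtained by iterating

$$W^{i+1} = \alpha\, W_{dd}\, W^i\, W_{tt} + (1-\alpha)\, W^0$$

from $W^0$. Both similarity layers are first degree-normalised,
$w(i,j) \leftarrow w(i,j)/\sqrt{\sum_k w(i,k)\sum_k w(k,j)}$, which bounds
the spectral radius of the propagation operator by one; for $\alpha < 1$
the map is then a contraction with a unique fixed point, and the iterate
converges geometrically at rate $\alpha$. The package verifies this
equivalence in its tests by solving the linearised system
$(I - \alpha\, W_{tt}^\top \!\otimes W_{dd})\,\mathrm{vec}(W) =
(1-\alpha)\,\mathrm{vec}(W^0)$ directly on small instances.

The decay factor $\alpha$ (unitless, in $(0,1]$) sets the balance between
propagated network signal and the original interactions. The default is
0.1: on sweeps across synthetic models (and in the package's decay-sweep
utility) small $\alpha$ dominates the AUC optima, consistent with heavy
class imbalance where anchoring to known links matters more than long-range
diffusion. `decayFactorSweep()` reproduces this analysis for any model set;
ties credit every tied value.

## Similarity kernels

* **Binary profiles** (fingerprint bits, drug–disease associations,
  drug–drug interactions, side effects, pathway memberships):
  Tanimoto $r_i \cdot r_j / (\|r_i\|^2 + \|r_j\|^2 - r_i \cdot r_j)$,
  Jaccard (identical functional form on binary vectors — the tests assert
  pointwise equality), and cosine $u \cdot v / (\|u\|\|v\|)$. Any pair
  involving an all-zero profile is defined as 0 off-diagonal to avoid
  $0/0$; every stored diagonal is 1 (maximal self-similarity).
* **PPI graph**: edges below a confidence threshold (default 0.5; the
  0–1000 integer dialect is detected and rescaled on read) are removed.
  The inverse-shortest-path measure applies $S = A e^{-bD}$ to hop
  distances $D$ computed breadth-first on the filtered graph, with
  $A = 0.9$, $b = 1$ per hop by default; unreachable pairs score 0. Hop
  counts (unit edge weights) are used rather than confidence-weighted
  paths: with unit weights Dijkstra's algorithm and breadth-first search
  coincide, and no principled edge-length scheme exists for confidence
  scores. The stored diagonal is 1 even though the raw transform gives
  $A$ at $D = 0$; `ispTransform()` exposes the raw transform.
  Common-neighbour measures apply Jaccard/cosine to binary adjacency
  vectors of the filtered graph.
* **Sequences**: Smith–Waterman (local) or Needleman–Wunsch (global)
  scores $s(a,b)$ via `Biostrings::pairwiseAlignment`, normalised to
  $s(a,b)/\sqrt{s(a,a)\,s(b,b)}$. Defaults are BLOSUM62 with gap open 10
  and gap extension 0.5. Global scores can be negative, so normalised
  values are clamped into $[0,1]$.

`measureCorrelations()` computes Pearson correlations over strict upper
triangles as a redundancy diagnostic; measures from one dataset correlate
strongly, which motivates the same-dataset exclusion rule below.

## Integration

Two matrices are combined elementwise (AVG, MIN, MAX) or fused nonlinearly
(SNF). An ordered set is folded *sequentially pairwise*: first two
combined, then each next measure combined with the running result. MIN and
MAX folds are order-invariant; the AVG fold weights late additions more
(three matrices give $A/4 + B/4 + C/2$), and SNF is likewise
order-dependent. Under forward selection the integration order is the
selection order, so the weighting favours measures added later — a
deliberate property of the sequential scheme rather than a bug. A
simultaneous $M$-view fusion is available through `snfFuse()` on a list of
matrices, but the sequential fold is the default used by the selection
wrapper.

SNF follows the semantics of the published reference implementations
(SNFtool / SNFpy): each view is row-normalised and symmetrised into a full
kernel; a row-normalised $k$-nearest-neighbour "dominate set" kernel $S$
is built (default $K = \min(20, n-1)$; neighbour ties at the $K$-th value
break by column order); each of $t = 20$ iterations updates
$P^{(m)} \leftarrow S^{(m)} \bar P^{(\neq m)} S^{(m)\top}$, adds the
identity to restore the diagonal, and symmetrises; finally the views are
averaged, row-normalised and symmetrised with a unit half-diagonal. Some
textbook presentations write the initial kernel with a half diagonal and
row sums over $k \neq i$; the reference implementations use plain row
normalisation, and this package follows the implementations — the test
suite pins the behaviour to an independent loop-level transcription of the
reference algorithm within $10^{-6}$. Because the fused scale is that of a
transition kernel rather than a similarity, the fused output of
`pairwiseCombine(..., "SNF")` is rescaled by its maximum off-diagonal
value before the diagonal is reset to 1, so downstream degree
normalisation sees a similarity-scaled matrix. One caveat this rescaling
does not remove: cross-diffusion *sharpens* similarity structure, so the
global ranking of weak pairs is not preserved — what is preserved (and
tested) is the separation of planted within-class pairs above
between-class pairs.

## Forward similarity integration

`forwardSimilarityIntegration()` is a greedy wrapper around the
cross-validated criterion (`AUPR` default, or `AUC`/`F1`). Step 1
evaluates all valid single-measure (drug, target) pairs. Later steps
evaluate three moves — joint best pair, drug-only, target-only — and accept
the best move only if it strictly improves the criterion; the trace is
therefore strictly increasing by construction. Stopping occurs at the
first non-improving step or when either remaining pool empties.

Design choices where the procedure is underdetermined:

* **Ties** in any argmax break by canonical catalog order (first declared
  wins), and ties between the three move types prefer drug-only, then
  target-only, then joint, following the order the acceptance conditions
  are checked in the algorithm's statement. Both rules exist purely for
  determinism; two runs with the same catalog, folds and configuration are
  bit-identical (asserted in tests).
* **Same-dataset exclusion** applies to the greedy candidates as well as
  to `enumerateValidCombinations()` — a candidate whose dataset tag is
  already represented on its side is skipped. The constrained enumeration
  of the reference layout (7 drug measures over 4 datasets, 9 target
  measures over 4 datasets) yields $53 \times 107 = 5{,}671$ valid
  combinations, which is the consistency check pinning this
  interpretation.
* **Fold reuse**: one `makeFolds()` assignment (stratified over positives
  and negatives separately, deterministic by seed) is shared by every
  candidate model, making wrapper comparisons paired.

Greedy search is not exhaustive search; on landscapes with a single
dominant informative pair the tests assert it reaches the exhaustive
optimum, but with several comparably informative, partially redundant
measures it can stop in a local optimum — an accepted property of forward
selection.

## Evaluation

Negatives are all unknown pairs (closed world). Per fold, the test-fold
positives are zeroed in the training $W^0$, propagation is run, and
metrics are computed on the test-fold pairs only. AUC uses the
rank-statistic (Mann–Whitney) formulation with average ranks for ties —
identical to trapezoidal ROC integration, and cross-checked against pROC
in the tests. AUPR uses step-wise non-interpolated precision integration
(average precision), the appropriate choice under prevalence of a few
percent. Thresholded metrics (PRE/REC/F1/ACC/MCC) need a decision rule the
propagation scores do not supply naturally; the default picks the
threshold maximising F1 on the evaluated pairs and reports it, with a
fixed-threshold alternative. MCC with a zero denominator is defined as 0.
Model comparisons use t-tests, paired across folds by default (the folds
are shared) and one-sided for improvement claims; zero-variance
differences degenerate to p = 1 (or 0 for a strict improvement) rather
than erroring.

## The synthetic benchmark

`syntheticSpec()`/`generateBundle()` plant latent classes: drugs and
targets are assigned classes cyclically; interactions are Bernoulli draws
from a class-compatibility matrix; each binary-profile dataset mixes class
prototypes (Bernoulli density 0.3) with noise at a per-dataset
informativeness in $[0,1]$, plus a flip-noise layer; the PPI graph
preferentially connects within-class targets with confidences above the
0.5 filter (plus low-confidence decoy edges below it); sequences descend
from class ancestors with point mutations. Binary prototypes with
Bernoulli flips were chosen over continuous features because every
similarity kernel here operates on binary vectors, graphs or sequences.

Defaults are desk-scale — 60 drugs × 80 targets, four classes, ~300
positives (prevalence ≈ 6%) — so a full forward-selection run takes
seconds; tests that need a sparser, sharper regime (order-of-magnitude
AUPR enrichment, held-out-link recovery) use ten classes with within-class
compatibility 0.35 and background 0.0005 (prevalence ≈ 3%). At
informativeness 0 every measure is uninformative and cross-validated AUC
sits at 0.5 within Monte-Carlo error; at informativeness 1 with no flip
noise, within-class profile similarity is exactly 1.

What passing on this benchmark does *not* show: real fingerprints, side
effects and PPI networks have heavy-tailed feature frequencies, correlated
features and hub structure that i.i.d. prototype flips do not emulate;
real similarity measures are far from conditionally independent given the
interaction structure; and real DTI networks are an order of magnitude
sparser (0.27% in the reference network of 862 drugs, 1,517 targets and
3,583 interactions) with degree heterogeneity the class model only
caricatures. Absolute metric values on the benchmark therefore do not
transfer to real data; the benchmark validates algorithmic correctness and
relative behaviour (signal vs. permuted/no-signal ablations, greedy vs.
exhaustive, decay-factor direction).

## Numerical choices and degenerate inputs

* Propagation stops when the max-absolute change falls below $10^{-6}$
  (cap 1000 iterations) — well below the score resolution that ranking a
  few thousand pairs requires; non-convergence is flagged on the result,
  and cross-validation treats it as an error naming the fold.
* Zero row sums in degree normalisation map to zero rows: isolated
  entities neither emit nor receive propagation. The unit self-similarity
  diagonal is included in the normalisation sums.
* Similarity matrices must be symmetric within $10^{-8}$ at construction;
  kernels enforce exact symmetry by averaging. The TSV reader repairs
  asymmetry up to $10^{-9}$ (warning above $10^{-12}$) and rejects worse.
* Entities present in the DTI network but absent from a data source keep
  zero profiles — similarity 0 to everything, diagonal 1 — rather than
  being dropped, so partial catalogs remain usable; `buildCatalog(...,
  intersect = TRUE)` instead restricts to entities covered by every
  source, reproducing the stricter convention of intersecting sources.
* All randomness (folds, sampling, the generator) flows through explicit
  integer seeds and restores the caller's RNG state.

## Known limitations

* Sequential SNF inherits order dependence from the fold; fusing all
  selected measures simultaneously is possible via `snfFuse()` but is not
  what the selection wrapper optimises.
* The closed-world negative assumption undercounts true positives among
  "negatives"; reported precision is pessimistic on real data.
* Forward selection cost grows as $|AD|\,|AT|$ in the first step; for
  catalogs much larger than the reference sixteen measures the wrapper,
  not propagation, dominates runtime.
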