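---
title: "Meta-path HeteSim scoring of small molecule–miRNA associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-path HeteSim scoring of small molecule-miRNA associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetesmir)
```

## The problem and the model

Many small molecules (SMs) modulate the expression of specific miRNAs, and
ranking candidate SM–miRNA pairs computationally narrows the space that wet-lab
screens must cover. `hetesmir` scores candidate pairs on a heterogeneous
network with two node types and three edge types:

* a binary adjacency matrix $A$ ($n_s \times n_m$) of experimentally supported
  SM–miRNA associations,
* an integrated SM–SM similarity matrix $SS$, and
* an integrated miRNA–miRNA similarity matrix $MM$,

both similarities symmetric, unit-diagonal, with entries in $[0,1]$. Each
relation is turned into a row-stochastic transition matrix:
$T_{sm} = \mathrm{rownorm}(A)$, $T_{ms} = \mathrm{rownorm}(A^\top)$,
$T_{ss} = \mathrm{rownorm}(SS)$, $T_{mm} = \mathrm{rownorm}(MM)$, where
$\mathrm{rownorm}$ divides each nonzero row by its sum and leaves zero rows
zero.

A *meta-path* is a typed node sequence from SM to miRNA; its **reachable
probability matrix** is the ordered product of the transition matrices along
it, so row $a$ is the distribution over end-type entities reachable from $a$.
The **HeteSim score** of a pair $(a, b)$ along a path $P = (P_L\,P_R)$ cut at a
middle type is the cosine

$$\mathrm{HeteSim}(a,b \mid P) =
  \frac{R_{P_L}(a,:) \; R_{P_R^{-1}}(b,:)^\top}
       {\lVert R_{P_L}(a,:)\rVert_2 \; \lVert R_{P_R^{-1}}(b,:)\rVert_2},$$

where $P_R^{-1}$ is the *reverse* of the right half-path, realized with the
opposite-direction transition matrices (the reverse of an association step is
$T_{ms}$, i.e. row-normalized $A^\top$ — **not** $T_{sm}^\top$; similarity
steps reverse onto $T_{ss}$/$T_{mm}$ again). Both vectors live in the
middle-type coordinate space, so the cosine compares how the two endpoints
reach the same set of intermediate entities.

All meta-paths from SM to miRNA with 2 or 3 relations are used — an exhaustive
set of six over two node types (two of length 2, four of length 3; see
`canonical_paths()`). A path with an even number of relations is cut at its
midpoint. A 3-relation path has no midpoint; both uneven cuts are scored and
averaged. The aggregated prediction is the length-decayed sum

$$S(a,b) = \sum_{l=2}^{3} \beta^{\,l-1}
           \sum_{P_i \in \psi_l} \mathrm{HeteSim}(a,b \mid P_i),$$

so the decay factor $\beta \in (0,1]$ down-weights the longer, more diffuse
paths. With all six per-path scores in $[0,1]$, $S$ is bounded by
$2\beta + 4\beta^2$.

Note that the direct length-1 path (the association edge itself) is excluded:
the sum runs over lengths 2 and 3 only, which is what lets the model score
pairs with no observed edge at all. One textual account of the method speaks
of "three" length-2 paths, but only two SM→miRNA type sequences of length 2
exist over two node types, and 2 + 4 = 6 matches the six-path aggregation;
`canonical_paths()` therefore enumerates exhaustively rather than following a
figure.

## Parameters that matter

* **`beta` (decay factor, unitless, default 0.5).** No published value exists
  for it; 0.5 is the package default — halfway down the admissible range, it
  halves the weight of each extra relation. `reference_evaluation()` sweeps a
  grid (default 0.1–0.9) so reproduction attempts need not trust the default.
* **`mode` (`"dataset1"` / `"dataset2"`).** `dataset1` indexes every entity
  named in the similarity matrices, so most SMs may have zero association
  degree and a zero $T_{sm}$ row; `dataset2` restricts to entities with at
  least one known association. Local (per-entity) ranking is easier in mode 1
  — a held-out pair competes mostly against isolated entities — which is why
  published AUCs differ sharply between the modes.
* **`self_loops` (default `TRUE`).** Whether similarity self-loops (the unit
  diagonal) survive into $T_{ss}$/$T_{mm}$. Keeping them is the default — the
  similarity matrices come with a unit diagonal and nothing in the method's
  definition removes it — and the switch exists for sensitivity analysis.

## Numerical conventions

* **Zero vectors score zero.** If either half-path vector of a pair is all
  zero the cosine is undefined; the score is set to 0, per cut, before the
  odd-path average. A never-associated, similarity-isolated entity carries no
  evidence, and this keeps every score finite.
* **Zero rows stay zero** under row normalization: a uniform row would
  fabricate reachability.
* Similarity asymmetries at or below $10^{-6}$ are averaged away on input and
  entries clamped to $[0,1]$; larger violations are fatal, never repaired.
* Ranking ties (in written predictions and in the case-study table) break
  lexicographically by identifier so runs are byte-reproducible.
* Cross-validation AUC is the mean per-holdout normalized rank of the test
  score against its candidate population, ties at half credit — equivalent to
  a pooled Mann–Whitney statistic over holdouts. Candidates are scored under
  the *same* masked network as the test pair (one prediction per holdout);
  the candidate universe is fixed by the full data (cells with no known
  association). Holdouts with an empty candidate population (possible in tiny
  networks under the local scopes) are skipped and counted in a warning.
* k-fold repeats derive their seeds as `seed + repeat index`, recorded in
  `config_echo`, so any single repeat can be reproduced in isolation.
* Scoring caches the association-independent products ($T_{ss}$, $T_{ss}^2$,
  $T_{mm}$, $T_{mm}^2$) once per network; holdout masking re-derives only
  $T_{sm}$/$T_{ms}$ and their products. The cache provably does not change
  results (the tests compare against an uncached explicit-loop oracle).

## What the synthetic generator emulates — and what it does not

`generate_synthetic_network()` plants the one statistical assumption the
method relies on: *similar entities share associations*. SMs and miRNAs are
assigned round-robin to matched blocks; associations are Bernoulli($p_{in}$)
inside a matched block and Bernoulli($p_{out}$) across; similarity entries are
uniform draws from a high within-block range and a disjoint low cross-block
range, symmetrized, unit diagonal. Defaults (40 SMs, 60 miRNAs, 4 blocks,
$p_{in}=0.3$, $p_{out}=0.01$, similarity ranges $(0.6,0.9)$ vs $(0.05,0.3)$,
seed 7) give a sparse matrix (density ≈ 0.09, close to real curated
association lists at desk scale) with strong, recoverable block signal, and a
full global LOOCV finishes in about a second. Setting $p_{in}=p_{out}$ and
identical similarity ranges removes the signal entirely — the sanctioned
negative control, expected to score AUC ≈ 0.5 (the control in the test suite
uses $p=0.1$, matching the default fixture's realized density, and the full
$(0.05,0.9)$ range for all similarities).

The generator does **not** mimic the heavy-tailed degree distribution of real
curated association databases, identifier semantics, or correlated noise
between the two similarity matrices. A green planted-signal test therefore
establishes that the engine recovers structure it is designed for — not that
any particular real dataset will reach a given AUC.

## Design choices that were genuinely open

* **Empty-set Jaccard is 0**, not 1: two annotation-free entities should not
  look identical.
* **Odd-path zeroing order:** zero-vector handling is applied per cut, then
  the two cuts are averaged (rather than averaging raw cosines and zeroing
  afterwards); the choice is isolated in one function.
* **Per-holdout candidate scoring:** every candidate is re-scored under the
  holdout's masking rather than once on the full data, so test and candidates
  face identical training information.
* **Dataset-2 restriction happens before normalization**, so its transition
  matrices are re-derived on the subnetwork rather than sliced out of the
  dataset-1 ones.

## Known limitations

* Reproducing published benchmark AUCs requires the original released
  association list and integrated similarity matrices; the package ships the
  protocol (`reference_evaluation()`) but not the data.
* The path family is fixed at lengths 2–3 with an unweighted within-length
  sum; no learned combination of path scores is provided.
* Everything is dense `base` linear algebra — appropriate up to a few
  thousand entities per type, not for genome-scale networks.
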