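---
title: "Layered ensemble structure learning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered ensemble structure learning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penbayes)
```

## The problem

A discrete Bayesian network couples a directed acyclic graph (DAG) over
categorical variables with one conditional probability table per node.
Learning the DAG from data by score-based search is well understood at
laptop scale, but a dataset with tens of millions of rows defeats a single
whole-data search: memory, time, and — less obviously — stability, because
two equally defensible learners frequently return different structures on
the same data. This package learns one structure from a large discrete
dataset by combining three ideas:

1. **Right-size the unit of learning.** A slice of the data that is too
   small is not faithful to the generating DAG; one that is too large wastes
   computation. The *appropriate learning size* (ALS) is estimated by a
   greedy doubling scheme (`calculate_als()`): learn on a leading slice,
   double it, and stop when two statistics of the learned structure — the
   average Markov blanket size (AMBS) and the edge strength — both move by
   less than a relative tolerance between doublings.
2. **Ensemble over algorithms.** On each slice, three constituent learners
   run: max-min hill climbing (`mmhc()`, a constraint/score hybrid), greedy
   hill climbing (`hill_climb()`), and tabu search (`tabu_search()`), all
   maximising the BDeu score. Their structures are merged by weighted edge
   voting with threshold factor 2 — a majority of three.
3. **Ensemble over data.** Each of `k` local learners merges its per-slice
   structures (threshold `n_slices / 2`), and the `k` local structures are
   merged once more (threshold `2k / 3`) into the final DAG.

Every merge is the same primitive, `structure_ensemble()`: weight each
candidate structure, sum the weighted adjacency matrices into a voting
matrix, and keep the edges whose vote strictly exceeds
`gamma = T * min(weight)`, adding them in descending vote order with a
cycle guard so the result is always a DAG.

## Scores and statistics

**BDeu.** `bdeu_log_score()` is the log marginal likelihood of the data
given the DAG under symmetric Dirichlet priors with equivalent sample size
`ess` (default 1; hyperparameter `ess / (r_i q_i)` per cell, where `r_i` is
the child's arity and `q_i` its number of parent configurations). The
uniform structure prior is a constant under comparison and is dropped. The
score decomposes over families and is equal across Markov-equivalent DAGs;
both properties are exercised by the test suite against a literal
transcription of the product formula and by exhaustive enumeration of the
25 three-node DAGs.

**Edge strength.** `edge_strength()` is `|log BDeu| / (N * M)` for a
structure with `M` edges on `N` records: the average per-record, per-edge
cost of the structure. Lower is better. It is the quantity used both to
weight ensemble candidates and to pick the representative "best" slice
carried into the higher merge layers. An edgeless structure has no
per-edge quantity; it gets an infinite edge strength and zero weight, so a
constituent that learns nothing simply casts no votes.

**Weight direction.** The candidate weight in `structure_weights()` is the
*normalised reciprocal* of edge strength. One could also read the
definition of a structure weight literally as edge strength over the sum of
edge strengths; we deliberately do not. With weights proportional to raw
edge strength the worst candidate receives the largest weight while the
voting threshold is keyed to `min(weight)` — the best candidate — and two
consequences follow that we observed directly on clean synthetic data:
(a) when two constituents return identical structures (hill climbing and
tabu search usually do), their common edges achieve a vote of exactly
`2 * min(weight)`, which fails a strict `>` threshold, and whole slice
merges collapse to the empty graph; and (b) orientation conflicts between
slices are resolved in favour of the worse-scoring side. With
quality-proportional weights the merge behaves as the majority rule the
threshold semantics describe ("an edge carried by more than `T`
structures' worth of minimal weight"), and the classic worked merge of
three 4-edge candidates with fixed weights (0.31, 0.34, 0.35),
`gamma = 0.62`, reconstructing the full 5-edge network, is unchanged,
since fixed weights bypass the weighting step.

**AMBS.** The average Markov blanket size (`ambs()`) is the mean over
nodes of |parents ∪ children ∪ co-parents|. It is constant across a
Markov-equivalence class (the skeleton fixes adjacent pairs, the
v-structures fix non-adjacent co-parent pairs), which is what makes it a
usable convergence statistic for ALS: it does not depend on which class
member a learner happens to orient.

## Search: determinism and its price

All searches start from the empty graph and use the operators add, delete,
reverse, with a strict BDeu improvement test (tolerance 1e-8) and no
random restarts, so every learner is a pure function of its input. Ties
within 1e-8 are broken add < delete < reverse, then by (parent, child)
index order.

The tie-break order matters more than it looks. The two orientations of a
*first* edge between any pair are always score-equivalent (an exact
mathematical tie), so some deterministic rule must pick one. Breaking ties
toward the lower-indexed *parent* orients tied additions along the column
order of the dataset. When columns are listed causes-before-effects — the
convention in benchmark network files — tied additions orient causally and
greedy search recovers the generating DAG; we verified exact recovery on
40/40 fixture slices. The mirrored rule (lower-indexed *child*) orients
every tied addition against the causal order on such files, seeds spurious
colliders, and drove hill climbing into a covered 6-edge local optimum on
more than half of fixture slices. The caveat is symmetric: on a dataset
whose columns happen to be ordered effects-before-causes, the preferred
rule inherits the bias, and it is the slice/algorithm/data ensembling —
not the tie-break — that must carry the robustness.

Plain hill climbing has one known, principled failure on small problems:
when the generating graph is a two-edge collider whose collision child
precedes its parents in column order, the optimum is two moves away
through a score-*equal* intermediate, and a greedy search that rejects
zero-gain moves cannot cross. Tabu search exists precisely for this: it
keeps a memory of recently visited structures (ten times `tabu_length`)
and, at a local optimum, accepts the best move to an unvisited structure,
stopping after a run of non-improving moves. In 400 randomized three-node
trials tabu search reached the exhaustive optimum in every run; hill
climbing alone in about 97%.

`mmhc()` first estimates an undirected skeleton with `mmpc()` (max-min
forward selection per node over G-squared conditional-independence tests,
conditioning sets up to size 3, `alpha = 0.05`, backward re-testing, AND
rule across endpoints), then hill climbs with additions restricted to the
skeleton. `exhaustive_search()` (at most five variables) is not a
practical learner; it is the oracle the others are tested against.

## The synthetic study system

There are no deposited datasets: every experiment forward-samples from a
known network, so ground truth is exact.

* `cancer_fixture(cpt_strength)` is the five-node respiratory-diagnosis
  network (Smoking → Bronchitis, Smoking → LungCancer, Bronchitis →
  Dyspnea, LungCancer → Dyspnea, LungCancer → Xray; true AMBS 12/5 = 2.4).
  The structure is classic; the tables are this package's own documented
  rule: the root is a fair coin, each single-parent child mirrors its
  parent with probability `cpt_strength` (default 0.9), and Dyspnea is a
  noisy OR of its two parents. One number therefore controls
  identifiability.
* `random_dag()` + `random_cpts()` draw arbitrary DAGs with symmetric
  Dirichlet tables — used wherever learning difficulty should *not* be
  controlled (scoring oracles, metric properties).
* `noisy_or_network()` parameterises a DAG in the classic noisy-OR family
  (per-parent activation strengths in [0.5, 0.9], leak 0.1). This is the
  generator for the search-oracle studies, because the whole framework
  presumes DAG-faithful data: symmetric-Dirichlet tables put an XOR-like
  collider on the graph — parents pairwise independent in sample — in
  roughly 8% of draws, and no single-edge greedy step can enter such a
  basin. That failure indicts the draw, not the search. Noisy-OR tables
  make every edge a monotone, marginally detectable dependence.
* `degrade_structure()` removes a fraction of a graph's edges and rewires
  half of the removed count to fresh acyclic positions — a model of a
  constituent learner going badly wrong.
* `forward_sample()` is plain ancestral sampling, deterministic per seed;
  sampled conditional frequencies converge to the table entries (checked
  at n = 100,000 within ±0.01).

What passing tests on these generators do *not* show: performance on data
with missing values, latent confounders, deterministic relationships,
selection bias, or column orders adversarial to the tie-break; nor
behaviour on networks wider than the guard on exact enumeration (the
pipeline itself has no such limit, but the oracle-backed guarantees do).

## Sizes, defaults, and why

| Parameter | Default | Meaning |
|---|---|---|
| `ess` | 1 | BDeu equivalent sample size; the common default of reference implementations. |
| `eps1`, `eps2` | 0.05 | Relative convergence tolerances for AMBS and edge strength in the doubling loop. |
| `initial_multiplier` | 50 | Records per attribute in the first slice: small enough to start below the appropriate size on easy networks, large enough for non-degenerate learning. |
| `mstep` | 20 | Doubling budget; `mstep = 0` returns the initial slice size, and the sentinel "best" values (AMBS 1, edge strength −1) force at least one doubling otherwise. |
| `alpha` | 0.05 | Independence-test level in the skeleton phase. |
| `tabu_length` | 10 | Tabu memory is 10× this; the stall limit is 2× this (at least 10). |
| `t_factor` | 2, `nd/2`, `2k/3` | Voting thresholds at the slice, local, and global layers: majority of three, majority of slices, two-thirds of locals. |

Degenerate inputs are defined, not accidental: an empty dataset scores 0;
an edgeless graph has infinite edge strength and zero weight; a merge in
which every candidate is edgeless returns the empty graph; a slice learner
whose constituents all fail raises an error, and one survivor is returned
with a warning; the doubling loop truncates with a flag when the dataset
is exhausted; remainder rows beyond `nd` equal slices join the last slice,
so no record is dropped.

The pipeline is a pure function of (data, configuration): local learners
share no state, so `workers = 8` and `workers = 1` return identical
adjacency matrices, and the work is `k * nd` slice-learner calls plus
`k + 1` merges — counted by instrumentation in the tests, not by
wall-clock.

## Study sizes used by the automated checks

The test suite and `scripts/acceptance.R` run end-to-end at: 400,000
records with `k = 4` learners for recovery (five replicates; expected
exact skeleton and at most one orientation difference); 50,000 records for
the size estimator (calculated AMBS within 10% of the true 2.4); ten
replicates of the slice-size sweep at ¼×, ½×, 1×, 2× the estimated size
(median structural Hamming distance non-increasing up to the estimate,
flat beyond); and ten replicates of the robustness study at 48,000 records
in which one local learner's max-min constituent is replaced by a
half-degraded version of itself (the final structure must be no further
from the truth than the intact runs'). These sizes exercise every layer
with several slices per learner while keeping a complete run on one core
in minutes.

## Known limitations

* The voting threshold compares votes to `gamma` strictly; candidates
  with *identical* structures produce exact weight ties, and an edge
  carried by exactly `T` tied minimal-weight structures is excluded by
  design (the majority must be strict).
* The appropriate size is estimated once, on the first learner's
  partition, and shared — matching a single preprocessing phase — so a
  heterogeneous (non-iid, ordered) dataset can mislead it; slices are
  leading prefixes by design and are not shuffled.
* Per-edge normalisation in edge strength favours denser structures when
  comparing candidates with different edge counts on the same data; it is
  a weighting heuristic, not a model-selection criterion.
* The exact learner is capped at five variables; beyond that all
  guarantees are heuristic.
* Orientation of tie-equivalent edges follows column order (see above);
  only skeleton and v-structures are identifiable from observational data
  in principle.
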