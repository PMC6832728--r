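# penbayes

Layered ensemble learning of discrete Bayesian-network structure from
large, partitioned datasets.

## The problem

Given `N` complete records over `P` categorical variables, structure
learning seeks the directed acyclic graph `G` maximising the BDeu score —
the log marginal likelihood of the data under symmetric Dirichlet priors,

```
log P(D | G) = Σ_i Σ_j [ log Γ(α_ij) − log Γ(α_ij + N_ij)
                         + Σ_k ( log Γ(α_ijk + N_ijk) − log Γ(α_ijk) ) ],
```

with `α_ijk = ess / (r_i q_i)`, where `N_ijk` counts records with child
`i` in state `k` under parent configuration `j`. At tens of millions of
rows a single whole-data search is slow, memory-bound, and unstable: two
defensible algorithms often return different graphs on the same data.

`penbayes` addresses this with three nested ensembles:

1. **Appropriate learning size (ALS).** A greedy doubling estimator finds
   the smallest data-slice size at which two statistics of the learned
   structure stabilise (relative change ≤ 5%): the average Markov blanket
   size `AMBS = Σ_i |MB(i)| / P` and the edge strength
   `ES = |log BDeu| / (N·M)` (M = edge count; lower is better).
2. **Slice layer.** On each ALS-sized slice, max-min hill climbing, hill
   climbing, and tabu search each learn a structure; the three are merged
   by weighted edge voting: candidate weights (normalised reciprocal edge
   strength) scale each adjacency matrix, the matrices are summed, and an
   edge survives if its total vote strictly exceeds
   `γ = T · min(weight)` with `T = 2` and never creates a cycle.
3. **Local and global layers.** Each of `k` local learners merges its
   slice structures the same way with `T = n_slices / 2`, and the `k`
   local structures are merged with `T = 2k / 3` into the final DAG.

Everything is deterministic given the data and seed; local learners are
independent, so the worker count never changes the result. Accuracy is
evaluated as structural Hamming distance (SHD: edge additions, deletions,
and reversals, a reversal counting one) against a known generating
network, with forward sampling from built-in or BIF/JSON-loaded networks
for simulation studies.

It is intended for researchers who need stable structure recovery from
big discrete data (sensor streams, patient monitoring, diagnosis-style
domains) on ordinary hardware, and for methodologists who want the
individual components — BDeu scoring, G² independence tests, MMPC, the
voting merge, the size estimator — as tested, composable functions.

## Worked example

Simulate from the built-in five-node respiratory-diagnosis network
(Smoking, Bronchitis, LungCancer, Dyspnea, Xray; 5 edges, true AMBS 2.4)
and learn it back with two local learners:

```r
library(penbayes)

gt  <- cancer_fixture(cpt_strength = 0.9)
sim <- forward_sample(gt$network, n = 60000, seed = 42)
fit <- run_penbayes(sim, k = 2)
fit
#> <penbayes_fit> 60000 records, 5 variables | k = 2, ALS = 500, 60 slice(s)/learner
#> final structure: 5 edges (17.5s total)

tidy(fit)
#> # A tibble: 5 × 4
#>   from       to         from_index to_index
#>   <chr>      <chr>           <int>    <int>
#> 1 Smoking    Bronchitis          1        2
#> 2 Smoking    LungCancer          1        3
#> 3 Bronchitis Dyspnea             2        4
#> 4 LungCancer Dyspnea             3        4
#> 5 LungCancer Xray                3        5

glance(fit)[, c("n", "p", "k", "als", "final_ambs", "nd", "n_edges")]
#> # A tibble: 1 × 7
#>       n     p     k   als final_ambs    nd n_edges
#>   <int> <int> <dbl> <int>      <dbl> <int>   <int>
#> 1 60000     5     2   500        2.4    60       5

shd(fit$graph, gt$network$graph)
#> [1] 0
```

Reading the output: the size estimator settled on slices of 500 records
(its convergence trace is in `fit$report$als`; `autoplot()` draws it),
each of the two local learners merged 60 slice-level three-algorithm
ensembles, the calculated AMBS (2.4) matches the generating network's,
and the final graph reproduces all five true edges exactly (SHD 0).
`autoplot(fit)` shows the global voting matrix with its threshold.

A shell entry point wrapping the same functions lives at
`inst/cli/penbayes.R`:

```sh
Rscript inst/cli/penbayes.R simulate --network cancer --n 60000 --strength 0.9 --seed 42 --out d.csv
Rscript inst/cli/penbayes.R learn --data d.csv --k 2 --out final.tsv --report report.json
Rscript inst/cli/penbayes.R eval --a final.tsv --b truth.tsv
```

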