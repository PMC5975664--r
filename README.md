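# branchgp

Branching Gaussian processes for gene-specific bifurcation times in
single-cell pseudotime.

## The problem

Trajectory-inference tools (Monocle-DDRTree, DPT, Wishbone, ...) order
single cells along a pseudotime axis and detect a *global* branching of the
cell population into two fates. Individual genes, however, do not all switch
on their fate-specific programmes at the global branching time: lineage-
priming genes diverge earlier, others later. `branchgp` is a downstream
analysis package for exactly this question: given pseudotime and a global
branching structure, *when does each gene's expression bifurcate, and how
sure are we?*

## The model

Each gene's expression profile over pseudotime is modelled with three latent
functions — a trunk `f` and two branches `g`, `h` — that share one
squared-exponential kernel `K` with signal variance σ² and lengthscale λ,
and are constrained to intersect at the gene's branching time `t_b`:

    f, g, h ~ GP(0, K),   f(t_b) = g(t_b) = h(t_b)

so that the covariance between different latent functions is
`K(t, t_b) K(t_b, t') / K(t_b, t_b)`. Which branch generated each
post-branch cell is unknown: a categorical assignment prior Π (built from
the global branching labels, with configurable confidence, uninformative
before the global branching time) is combined with the Gaussian likelihood
`N(Y | ZF, σ²I)` and the assignments are integrated out with a mean-field
variational posterior Φ, giving a *collapsed* evidence lower bound that is
maximised over Φ and the hyperparameters. A Titsias-style inducing-point
approximation gives O(k²N) scaling. Evaluating the evidence on a grid of
candidate branching times yields, per gene:

- a posterior distribution over `t_b` with a smallest-window credible
  interval,
- a log Bayes factor `r_g = log[mean_c p(Y|t_b = c)] − log p(Y|t_b → ∞)`
  for branching versus not branching,
- posterior assignment probabilities Φ per cell, and predictive branch
  curves.

Posterior samples of branching times drive two downstream summaries: a
directed *branch-order network* (edge A→B when gene A branches before gene
B with probability above a confidence cut-off) and per-gene posterior
*rank* distributions.

## Worked example

Simulate a small branching dataset with known truth and fit one early- and
one late-branching gene:

```r
library(branchgp)

cfg <- synthetic_config(
  n_cells = 150,
  gene_groups = data.frame(branch_time = c(0.2, 0.8, NA),
                           n_genes = c(1L, 1L, 1L)),
  noise_variance = 0.001, seed = 7)
ds <- make_benchmark(cfg)

fit <- fit_gene(ds$expr[1, ], ds$global,
                bgp_config(prior_confidence = 0.8), gene_id = "early")
fit
#> BGP fit for early (N = 150): log BF = 367.40, MAP branching time = 0.1983,
#> 98% CI [0.1983, 0.1983]
```

The true branching time of this gene is 0.2: the maximum-a-posteriori
estimate lands on the nearest grid candidate (0.1983, a zero-width
credible interval at this near-noiseless setting) and the log Bayes
factor (367) is overwhelming evidence of branching. The same call on the
non-branching gene in `ds` returns a *negative* log Bayes factor (−3.8),
i.e. the single-trajectory model is preferred. `summary()` over a
`fit_genes()` result collects `gene_id`, `map_time`, the credible interval
and `bayes_factor` into a table; `build_order_network()` and
`posterior_rank()` consume the fits directly.

The benchmark harness regenerates the standard simulation design (150
cells; genes branching at 0.2 and 0.8 plus non-branching genes; σ² = 2,
λ = 1.2; Gaussian noise) and scores detection AUC and branching-time RMSE
against the ground truth:

```r
run_benchmark(noise_levels = 0.001, n_replicates = 1, scale = 0.3, seed = 1,
              prior_modes = "informative")
#>   noise  prior_mode replicate auc       rmse n_genes n_failed seed
#> 1 0.001 informative         1   1 0.01374343      12        0 1141
```

At this noise level every branching gene is separated from every
non-branching gene (AUC = 1) and branching times are recovered to about one
hundredth of the pseudotime range.

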