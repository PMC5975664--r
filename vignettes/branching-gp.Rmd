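---
title: "Branching Gaussian processes for gene-specific bifurcation times"
author: "branchgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching Gaussian processes for gene-specific bifurcation times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`branchgp` asks, for each gene independently: given per-cell pseudotime and
a dataset-wide (global) branching structure estimated upstream, at which
pseudotime does *this gene's* expression bifurcate, and how strong is the
evidence that it bifurcates at all?

Three latent functions — a trunk $f$ and two branches $g, h$ — carry a
shared zero-mean Gaussian-process prior with a squared-exponential kernel
$K(t,t') = \sigma_s^2 \exp\{-(t-t')^2/(2\lambda^2)\}$ and are constrained
to intersect at the branching time $t_b$:

$$f,g,h \sim \mathcal{GP}(0, K), \qquad f(t_b) = g(t_b) = h(t_b).$$

Conditioning on the shared value at $t_b$ gives the cross-covariance
$K(t, t_b)K(t_b, t')/K(t_b, t_b)$ between any two of the functions; the
joint covariance over an augmented input set (each cell replicated for each
latent function) is returned by `branching_cov()`. Two consequences the
test suite verifies directly: $\mathrm{Var}[f(t_b) - g(t_b)] = 0$, and as
$t_b \to \infty$ the functions decouple into an overlapping mixture of
independent GPs — this limit *is* the non-branching model. Latent-function
derivatives are not constrained at $t_b$, so branch paths may leave the
trunk with a kink; constraining derivatives would be a kernel-level
extension, not attempted here.

Each observation is generated by exactly one latent function,
$p(Y\mid F, Z) = \mathcal{N}(Y \mid ZF, \sigma^2 I)$ with a one-hot
indicator row per cell and a categorical prior $p(Z) = \prod_{n,m}
\Pi_{nm}^{Z_{nm}}$. The assignment prior built by `assignment_prior()`
encodes the global structure:

* cells before the candidate branching time are deterministically trunk —
  only one latent function exists there;
* cells after both the candidate time and the global branching time get
  probability $c$ on their globally labelled branch and $1-c$ on the other
  ($c$ = `prior_confidence`, default 0.99; 0.5 disables the information);
* cells after the candidate time but before the global branching time have
  no usable label and get $(0.5, 0.5)$ over the branches.

## Collapsed variational bound

The exact evidence requires summing $Z$ over $2^{n_{\text{post}}}$
configurations. With a mean-field posterior $q(Z) = \prod_{n,m}
\Phi_{nm}^{Z_{nm}}$ and the GP integrated out analytically, the collapsed
bound is

$$L_2 = -\tfrac{N}{2}\log(2\pi\sigma^2) - \tfrac{Y^\top Y}{2\sigma^2}
 - \tfrac12\log|K| - \tfrac12\log\bigl|A\sigma^{-2} + K^{-1}\bigr|
 + \tfrac12\sigma^{-4} Y^\top\Phi\,(A\sigma^{-2}+K^{-1})^{-1}\Phi^\top Y
 - \mathrm{KL}[q(Z)\,\|\,p(Z)],$$

where $A = \mathbb{E}_q[Z^\top Z]$ is diagonal in the augmented
representation. `collapsed_bound()` never forms $K^{-1}$; it uses the
algebraically equivalent pseudo-observation form
$-\tfrac12\log|I + SKS| - \tfrac12 e^\top (I + SKS)^{-1} e$ with
$S = A^{1/2}/\sigma$ and $e = S\,y$, restricted to the prior's support.
This matters: the textbook expression subtracts two $\sigma^{-4}$-scaled
quadratic forms and loses *all* significant digits once $\sigma^2$ is
small, whereas the pseudo-observation form keeps every intermediate at
$O(\sigma^{-2})$ or below and reduces exactly to the Gaussian-process log
marginal likelihood when all assignment mass sits on one function (a unit
test asserts equality to an independent multivariate-normal density).

`sparse_collapsed_bound()` is the Titsias-collapsed analogue: the Nyström
approximation $Q = K_{xu}K_{uu}^{-1}K_{ux}$ replaces $K$ inside the bound
and the weighted trace correction $\mathrm{tr}[A(K-Q)]/(2\sigma^2)$ is
subtracted, at $O(k^2N)$ cost for $k$ inducing pseudotimes (quantile-placed,
replicated across the three latent functions, frozen during optimisation;
$k = 30$ by default, with sparse inference engaging automatically once the
augmented representation exceeds $3k$). The diagonal jitter is treated as a
white-noise kernel component shared by exactly coinciding inputs, so the
sparse bound equals the full bound to machine precision when the inducing
set is the data set, and is below it for proper subsets — both properties
are asserted over randomised instances, as is the defining guarantee that
the optimised bound never exceeds an exact evidence computed by brute-force
enumeration of $Z$ on small instances.

## Optimisation

The bound is maximised by alternating

1. exact mean-field fixed-point updates of $\Phi$ — each row is the softmax
   of $\log\Pi_{nm} - (\mathbb{E}[f_j^2] - 2y_n\mathbb{E}[f_j])/(2\sigma^2)$
   over the prior support, which is provably monotone in the collapsed
   bound (coordinate ascent with the optimal $q(F)$ profiled out), and
2. bounded quasi-Newton (L-BFGS-B, finite-difference gradients) over the
   three log hyperparameters $(\log\sigma_s^2, \log\lambda, \log\sigma^2)$
   at fixed $\Phi$,

until the bound improves by less than `outer_tol`. This scheme was chosen
over joint gradient ascent on a softmax parameterisation of $\Phi$ because
exact coordinate updates are available in closed form, guarantee a
monotone trace (asserted in tests), and need no automatic differentiation;
the trade-off is discussed under *Limitations*. Initialisation is
deterministic: $\Phi = \Pi$, lengthscale 0.3 of the pseudotime range,
signal variance the sample variance, noise variance a quarter of it. The
noise variance is floored at $10^{-6}\times$ the sample variance and the
expression vector is centred (the GP prior is zero-mean). Pseudotime is
min–max rescaled to $[0,1]$ internally; all reported times are on the
original scale.

## Per-gene quantities

`fit_gene()` evaluates the bound on `n_candidates` (default 20) equally
spaced candidates over the central 90% of the pseudotime range,
warm-starting hyperparameters along the grid, and fits the non-branching
model by the same machinery with the branch point at infinity and an
all-trunk prior (algebraically the single-GP marginal likelihood, with its
own hyperparameters). The bound values stand in for $p(Y \mid t_b = c)$ —
they are lower bounds used as marginal-likelihood surrogates:

* posterior over $t_b$: softmax of the per-candidate log evidence
  (equal candidate prior), computed with max subtraction;
* log Bayes factor: $r_g = \log[\frac{1}{N_b}\sum_c p(Y|t_b\!=\!c)] -
  \log p(Y|t_b\!\to\!\infty)$ via log-sum-exp;
* credible interval: the *smallest contiguous* grid window holding the
  requested mass (default 98%), ties resolved toward earlier times — a
  deliberate match to the one-sided uncertainty typical of branching
  posteriors, which are sharp on the late side and flat on the early side;
* `predict_branches()`: Gaussian predictive means and variances of all
  three functions under the MAP-candidate model, using the assignment
  posterior as observation weights.

Genes are independent work units; `fit_genes()` results do not depend on
fitting order, and per-candidate failures are counted rather than fatal
(a gene is flagged when more than half its candidates fail). No
multiple-testing correction is applied to Bayes factors; the evidence
cut-off used downstream is exposed as a parameter (0 selects "any
evidence"; larger values such as 50–500 select high-confidence sets).

`t_filter()` provides the usual pre-selection step for large panels: a
Welch $t$-statistic between branch end states (the latest quarter of each
branch's cells by default), keeping genes with $|t|$ above a threshold.

## Downstream summaries

`posterior_samples()` draws from the discrete grid posterior, so ties
between genes are possible and count as "not before".
`prob_gene_before_gene()` uses the all-pairs (U-statistic) estimator over
two independent sample sets; $P(A\!<\!B) + P(B\!<\!A) + P(\text{tie}) = 1$
holds exactly. `build_order_network()` draws `S = 5000` samples per selected
gene and keeps directed edges at or above the confidence cut-off (default
0.95), which rules out 2-cycles by construction. `posterior_rank()` ranks
genes within each joint draw (random tie-breaking preserves
exchangeability on the discrete grid) and reports median ranks with central
95% quantiles.

## Synthetic data and benchmark

`make_benchmark()` emulates the study conditions the model targets:
sorted-uniform pseudotimes on $[0,1]$; a dataset-level branch membership
(one fair coin per cell, shared by all genes, so that a single global
branching structure is meaningful); per-gene draws from the constrained
branching prior with $\sigma_s^2 = 2$, $\lambda = 1.2$; additive Gaussian
noise. Latent draws in which the two branches cross again after the
branching point are rejected and redrawn (at the resolution of the observed
pseudotimes — only observable crossings can confuse an estimator); the
pre-branch law is unaffected, which a Monte-Carlo test checks against the
kernel. The default design is 150 cells and 40 genes: 10 branching at 0.2,
20 at 0.8, 10 non-branching; an alternative 3-at-0.1 / 27-at-0.7 / 10
non-branching configuration exercises the early/late bias regime. The
generator's global structure is the oracle: true memberships and the
earliest true branching time; `corrupt_global_labels()` emulates imperfect
upstream assignment by flipping post-branch labels. Everything is
reproducible from a single seed (R's default Mersenne-Twister RNG).

What the generator does *not* emulate: count noise, zero inflation,
dropout, pseudotime estimation error beyond label flipping, and
gene–gene correlation beyond the shared membership. Passing benchmarks
therefore demonstrate correctness of the inference under the model's own
assumptions, not robustness to real single-cell artefacts.

`run_benchmark()` scores detection (rank-based AUC of the log Bayes factor
against the true branching flag) and estimation (RMSE of the MAP time over
truly branching genes) per noise level, prior mode (informative 0.8 versus
uninformative 0.5) and replicate. The `scale` argument shrinks gene counts
proportionally; the packaged tests and the acceptance script use
`scale = 0.3` (3/6/3 genes) with 1–3 replicates to keep a full run in
minutes on one CPU, and the harness supports `scale = 1` replicating the
full 40-gene design when more time is available.

## Numerical choices

* Jitter: $10^{-6}\sigma_s^2$ on covariance diagonals before Cholesky
  factorisation; an ill-conditioned sparse system retries at $100\times$
  jitter before erroring.
* Noise floor: $10^{-6}\times$ sample variance, preventing degenerate
  likelihood spikes from the mixture's ability to shadow individual points.
* Support restriction: all linear algebra runs on the expanded indices
  where the prior is positive — exact, and roughly halves the cost.
* Degenerate inputs: zero-range pseudotime, non-finite expression,
  out-of-range confidences and malformed priors raise validation errors;
  all-failed candidate grids abort the gene with a message.
* Ties in pseudotime are allowed everywhere except between an inducing
  point and a distinct data point at identical (time, label) pairs, where
  the shared-jitter convention applies.

## Limitations

* **Flat early-side posteriors at high noise.** A candidate earlier than
  the true branching time nests the truth (the branches may simply stay
  together for a while), so the evidence surface is inherently one-sided:
  sharp above the true time, flat below it. At low noise the Occam terms
  penalise the extra flexibility and the posterior concentrates; at high
  noise (variance comparable to the squared branch separation) the flat
  region widens, MAP estimates of weakly identified genes drift toward the
  lower grid edge, and credible intervals widen accordingly. Re-optimising
  hyperparameters per candidate — necessary for the evidence to be a
  profile likelihood in the hyperparameters — adds a small
  empirical-Bayes preference for the more flexible early candidates that
  sharpens this drift. The credible interval, not the MAP point, is the
  honest summary in that regime.
* **Exact mean-field optimisation can exploit assignment freedom.** With a
  fully uninformative prior the converged $\Phi$ may split cells between
  near-identical branch functions to shadow observation noise, degrading
  evidence calibration; an informative prior (0.8–0.99) suppresses this
  and is strongly recommended. Joint (non-coordinate) ascent schemes that
  keep $\Phi$ near its initialisation behave differently in exactly this
  regime.
* One branching point per gene; Gaussian likelihood on (log-scale)
  expression; pseudotime treated as known. Multiple branchings,
  count likelihoods and joint pseudotime inference are out of scope.
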