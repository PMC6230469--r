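---
title: "Sampling the posterior over single-cell orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling the posterior over single-cell orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gporder)
```

## The model

Single-cell RNA-seq destroys the cell it measures, so a developmental
process is observed only as a cross-section: many cells, each a snapshot
at an unknown stage. Pseudotime methods order the cells so that neighbours
in the ordering are neighbours in expression space. Most return a single
ordering; `gporder` instead samples the *posterior distribution over
orderings*, because the data often support many orderings almost equally
well, and the width of that posterior varies along the process — batches of
interchangeable cells ("metastable states") produce wide position
distributions, fast transitions produce narrow ones.

The sampled object is a permutation $o = (o_1,\dots,o_T)$ of the $T$ cells.
Given $o$, each gene's reordered expression vector $y_g(o)$ is modelled as
one draw from a shared zero-mean Gaussian process over pseudotimes
$\tau(o) \in [0,1]^T$ with squared-exponential covariance

$$\Sigma_{ij} = \sigma_w^2 \exp\!\Big(-\frac{(\tau_j-\tau_i)^2}{2\,l^2}\Big)
  + \delta_{ij}\,\sigma_\epsilon^2 ,$$

so the marginal likelihood of $o$ is a product of $n_g$ multivariate-normal
densities sharing one Cholesky factorization. Pseudotimes are a
*deterministic function of the ordering*:

* **geodesic mapping** (default): cumulative Euclidean distances between
  consecutively ranked cells, rescaled to $[0,1]$. Locally adaptive — cells
  similar in expression sit close in pseudotime.
* **rank time**: the equidistant grid $((i-0.5)/T)$. Used for the
  simulation studies so that results reflect the order moves alone.

Sampling orderings rather than continuous pseudotime vectors avoids
exploring the continuum of pseudotime assignments that map to the same
ranking, and the deterministic mapping pins the scale.

## Priors and what they assume

The total sample variance $V$ of the centered matrix is split as
$\sigma_\epsilon^2 = V - \sigma_w^2$, so only $\sigma_w^2$ and $l$ are
sampled. Defaults (all on the log scale, all overridable in
`prior_spec()`):

| parameter | prior | rationale |
|---|---|---|
| $\log \sigma_w^2$ | $N(\log 0.9V,\ 0.1^2)$ | ~90% of variance attributed to signal; single-cell noise is high but the *ordering* signal must dominate for the problem to be identifiable |
| $\log l$ | $N(\log 0.5,\ 0.1^2)$ | tight: a vague length-scale prior lets the GP overfit noise with short wiggles |

The printed source for the signal prior is ambiguous between a law on
$\log\sigma_w$ and on $\log\sigma_w^2$; the package parametrizes
$\log\sigma_w^2$ (the `"sd"` reading is available via
`signal_scale = "sd"`). Either way the prior is truncated at
$\sigma_w^2 < V$ (about 15% of prior mass is rejected at the default
settings), which keeps the noise variance strictly positive. The prior
over orderings is uniform, so it cancels from every acceptance ratio.

## The proposal moves

Five symmetric kernels, mixed with probabilities $p_1..p_5$
(`move_config()`), defaults: moves 1–4 equiprobable, move 5 at 0.002:

1. **iterated neighbor swaps** — up to $n_0 = \lfloor T/4\rfloor$ adjacent
   transpositions;
2. **distance-weighted swap** — a cell pair is drawn with probability
   $\propto \exp(-d^2/\gamma)^\alpha$ ($d$ = L1 distance of the two
   expression profiles) and exchanged;
3. **distance-weighted segment reversal** — same pair law; the segment
   between the two cells is reversed;
4. **short random permutations** — up to $n_3 = \lfloor T/20\rfloor$
   segments of $r_3+1$ cells ($r_3 \le \max(n_{3a},3)$,
   $n_{3a} = \lfloor T/12\rfloor$) are independently shuffled;
5. **full reversal.**

Moves 2/3 are symmetric because every unordered cell pair occupies exactly
one position pair under any ordering: the proposal normalizer is
order-invariant and the selected pair's weight survives the move. This is
asserted empirically (exhaustive enumeration of the transition counts at
$T = 4,5$) rather than assumed. With symmetric proposals and a uniform
order prior, the Metropolis–Hastings ratio is the likelihood ratio alone.

$\gamma$ defaults to the median squared pairwise L1 distance, which makes
the pair weights scale-free; $\alpha < 1$ tempers the weights when
acceptance must be lowered. Move 5 deserves a note: the posterior is
exactly symmetric under full reversal (both pseudotime mappings preserve
$|\tau_i - \tau_j|$), so every run — including single-move benchmark runs —
keeps move 5 at probability 0.002. Without it a chain is confined to one of
the two mirror-image modes and the between-chain variance of
position-based summaries never shrinks; with it chains hop modes freely and
the mirror symmetry is removed *afterwards* by `resolve_reversals()`,
which flips every stored order whose positions correlate negatively
(Spearman) with the capture times or a marker gene.

## The sampler

Each iteration makes one order proposal and then (unless the
hyperparameters are fixed) one joint Gaussian random-walk proposal on
$(\log\sigma_w^2, \log l)$, accepted as a block — one likelihood evaluation
per iteration, a simple valid Metropolis-within-Gibbs schedule. During the
first half of the run (burn-in) the proposal sds adapt every 100 proposals:
×1.1 if the windowed acceptance exceeds 0.5, ×0.9 below 0.45. Adaptation
freezes at the end of burn-in, preserving ergodicity; asking for it later
is an error by contract. On simulated benchmark data this lands the
realized post-burn-in acceptance at ≈0.48 (9/10 seeds ≥ 0.45).

Starting orders are uniform permutations *within* capture-time blocks
(blocks concatenated in capture-time order); this biases nothing — it is a
starting-point restriction only — and speeds convergence because
cross-capture-time misplacements are rare under the posterior.
Hyperparameters start at a prior draw. Chains are identified by their
integer seed; identical seeds give bit-identical results.

Numerical choices: one upper-triangular Cholesky factor is shared by all
genes per likelihood; if factorization fails, jitter starting at
$10^{-10}\,\mathrm{tr}(K)/T$ escalates tenfold up to $10^{-6}$ before a
parameter-naming error. When rank time is combined with fixed
hyperparameters (the simulation-study regime) the inverse covariance is
precomputed once, reducing each likelihood to one matrix product. Duplicate
cells are legal: $\sigma_\epsilon^2 > 0$ keeps the covariance positive
definite even with tied pseudotimes.

## Convergence protocol

`assess_convergence()` follows the multiple-chain protocol: at
logarithmically spaced sample counts, discard the first half of the thinned
samples and compute the corrected potential scale reduction factor
(`gelman_rubin()`, the $(d+3)/(d+1)$ sampling-variability correction,
transcribed in the documentation so tests can check it against an
independent implementation) on two scalar summaries — the log-likelihood
and the L1 distance of the cell positions from a reference permutation
(the true order on simulated data, identity otherwise). Both must fall
below 1.1, the stricter of the two conventional thresholds. Chains frozen
at a constant value yield a flagged `NA`, never a spurious "converged".

On data simulated from the two-capture-time benchmark design (90 cells,
50 genes, blocks 30/60), five chains of 100,000 iterations (thinning 10)
using the segment-reversal move alone reach both statistics < 1.1 within
the first 10,000 thinned samples — the behaviour the move was designed
for, reproduced by `simulation_study("sim2", dataset_seed = k)` and
asserted in the acceptance tests at that exact size.

## Posterior summaries

`summarize_posterior()` recomputes pseudotimes per stored draw and reports
per-cell mean and sd of pseudotime, the row-stochastic cell × rank
position-frequency matrix, and a modal ordering (cells sorted by mean
pseudotime; exact posterior modes over $T!$ permutations are not
computable). `mds_positions()` embeds draws (as position vectors) by
classical MDS of their Euclidean distances — clouds with several dense
areas indicate multimodal posteriors. `gene_set_score()` plots a
known program (e.g. an antiviral response signature) against mean
pseudotime as a biological sanity check.

## Mini-cluster approximation

For thousands of cells the $T!$ space and the $O(T^3)$ factorization both
bite. `build_miniclusters()` k-means-clusters cells *within* each capture
time (default: $\max(5, n_t/8)$ clusters per capture time, 10 restarts,
seeded), the sampler runs on the centroid matrix (whose total variance is
recomputed, since the likelihood operates on centroids), and
`expand_pseudotimes()` hands each cell its centroid's posterior summary.
With one cell per cluster the pipeline is *exactly* the full method (no
k-means is run; this degenerate path is tested). On 300-cell synthetic
data the exact and approximate per-cell mean pseudotimes correlate > 0.9.

## The synthetic-data generator

`simulate_dataset()` draws input times uniformly on $[0,1]$, per-gene GP
hyperparameters from log-normal laws, each trajectory from the noise-free
kernel plus iid $N(0, \sigma_\epsilon^2)$ noise (equivalent to one draw
from the full kernel — stated for oracle writers), assigns capture-time
labels by time-sorted blocks and returns shuffled cells plus the
generating permutation. The three presets encode the benchmark designs
(50 genes × 90 cells; three blocks of 30 / blocks 30+60 / high noise with
$\log\sigma_\epsilon \sim N(0, 0.1)$). Printed dispersions are read as
variances — the standard N(mean, variance) convention, matching the prior
section; the benchmark convergence result is insensitive to this choice
(both readings were run).

What the generator does *not* emulate: count noise and dropout, library-size
variation, branching trajectories, batch effects. Tests passing on this
generator therefore validate the sampler and its summaries, not robustness
to real scRNA-seq artifacts; on real data the ANOVA/mean-variance gene
filters and the cell-size adjustments cited in the source literature do
that work.

## Problem sizes used in the tests

Chosen once as desk-scale study conditions: the convergence study runs the
full published size (3 datasets × 5 chains × 100,000 iterations); the
exhaustive-posterior oracle uses $T=5$, $n_g=3$ with $5\times10^5$
iterations against all 120 enumerated permutations (total variation
< 0.05); order recovery uses a reduced design ($T=30$, $n_g=20$); the
mini-cluster comparison uses 300 cells with 60,000 iterations per
pipeline, rank time, hyperparameters fixed at their generating medians.

## Known limitations

* At 20 genes and $\sigma_\epsilon = 0.5$ adjacent cells are only ~0.5 sd
  apart in expression, so posterior-mean positions cannot exceed
  Kendall ≈ 0.9 against the generating order no matter how long the chains
  run — order-recovery summaries on few genes measure the data's
  information content, not sampler quality.
* The likelihood shares one $(\sigma_w^2, l, \sigma_\epsilon^2)$ across
  genes; strongly heterogeneous gene kernels are averaged over.
* Gaussian likelihood on log-transformed data; counts are not modelled
  directly.
* Linear trajectories only — no branching.
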