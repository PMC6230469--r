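# gporder — Bayesian sampling of single-cell orderings

Pseudotime methods reconstruct the progression of a biological process
from destructive single-cell snapshots by ordering cells so that neighbours
in the ordering are neighbours in expression space. Most tools return one
ordering. `gporder` samples the **posterior distribution over orderings**
(permutations of cells), for analysts who need to know not just *an* order
but *how certain* each cell's position is: posterior position spread
identifies metastable phases, experimental batch effects, and "precocious"
cells running ahead of their capture time, and tells you which cells are
safe inputs for downstream network or clustering analyses.

## Model

For an ordering $o$ of $T$ cells, pseudotimes $\tau(o) \in [0,1]^T$ are a
deterministic map of the ordering — either the *geodesic* map (cumulative
Euclidean distances between consecutively ranked cells, normalized) or
*rank time* $((i-0.5)/T)$. Each of the $n_g$ genes' reordered expression
vectors is modelled as an independent draw from one zero-mean Gaussian
process with squared-exponential covariance

$$\Sigma_{ij} = \sigma_w^2\, e^{-(\tau_j-\tau_i)^2 / 2l^2} + \delta_{ij}\sigma_\epsilon^2,
\qquad \sigma_\epsilon^2 = V - \sigma_w^2,$$

where $V$ is the total variance of the centered matrix. A
Metropolis–Hastings sampler explores the permutation space with five
symmetric proposal moves (iterated neighbor swaps; distance-weighted pair
swap; distance-weighted segment reversal; short random segment
permutations; full reversal), while $(\log\sigma_w^2,\log l)$ get an
adaptive Gaussian random walk under informative log-normal priors.
Convergence is assessed with the corrected Gelman–Rubin statistic on the
log-likelihood and on L1 position distances across independently seeded
chains; a k-means mini-cluster approximation (clusters built within
capture times, 1/8 of the cells each) scales the method to thousands of
cells. The methods vignette (`vignettes/ordering-uncertainty.Rmd`) gives
the full account of the model, priors, moves and numerical choices.

## Worked example

Simulate a 30-gene, 40-cell trajectory with two capture times, run three
chains, check convergence, resolve the mirror symmetry and summarize:

```r
library(gporder)
sim  <- simulate_dataset(simulation_spec(n_genes = 30, n_cells = 40,
                                         blocks = c(20, 20), log_eps_sd = 0.1),
                         seed = 8)
expr <- center_data(sim$expr)
chains <- run_chains(expr, seeds = c(11, 12, 13), n_iter = 20000, thin = 10)
assess_convergence(chains, reference = sim$true_order)
#> convergence report (threshold 1.10): converged
#>  sample_count rhat_loglik rhat_l1 converged
#>           ...         ...     ...       ...
#>          1199       1.065   1.060      TRUE
#>          2000       1.010   1.008      TRUE

chains <- resolve_reversals(chains, as.numeric(expr$capture_times))
summ   <- summarize_posterior(chains, expr)
summ
#> posterior summary over 3000 draws (geodesic pseudotime)
#>   cell_id mean_pseudotime sd_pseudotime
#>  cell_001         0.76908       0.02484
#>  cell_002         0.35817       0.02306
#>  cell_003         0.24364       0.03124
#>  ...
```

Both R-hat statistics drop below 1.1, so the three chains agree on the
posterior. Each cell gets a posterior mean pseudotime in [0, 1] and a
standard deviation quantifying how interchangeable its position is with
its neighbours'; `summ$position_freq` holds the full cell × rank
distribution and `mds_positions(chains)` embeds the sampled orderings to
reveal multimodality. Here the posterior mean positions reproduce the
generating order with Kendall τ = 0.938:

```r
cor(as.numeric(summ$position_freq %*% seq_len(40)),
    order(sim$true_order), method = "kendall")
#> [1] 0.9376923
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "gporder", package = "gporder")` with subcommands
`simulate | run | converge | summarize | minicluster`.

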