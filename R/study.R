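#' Simulation-study convergence protocol
#'
#' Runs the benchmark protocol on one simulated dataset: generate the
#' preset dataset, center it, fix the GP hyperparameters at their
#' generating medians, use rank time, run independently seeded chains with
#' the requested subset of moves 1-4 (equal probabilities, plus the full
#' reversal at probability 0.002 as in every study run), and assess the
#' corrected Gelman-Rubin statistics of the log-likelihood and of the L1
#' position distance to the true order, discarding the first half of the
#' thinned samples.
#'
#' @param preset preset name (see [simulation_presets()]) or a
#'   `simulation_spec`.
#' @param dataset_seed seed of the simulated dataset; chain seeds default
#'   to `dataset_seed * 1000 + 1:n_chains`.
#' @param moves integer subset of 1:4 to use (default 3, the segment
#'   reversal move).
#' @param n_chains,n_iter,thin chain settings; defaults follow the study
#'   protocol attached to the presets (5 chains, 100,000 iterations,
#'   thinning 10).
#' @param threshold convergence threshold (default 1.1).
#' @param chain_seeds optional explicit chain seeds.
#' @return list with the `convergence_report`, the maximum of the two
#'   final statistics (`max_rhat`), the dataset and the chains.
#' @export
simulation_study <- function(preset = "sim2", dataset_seed, moves = 3,
                             n_chains = 5, n_iter = 100000L, thin = 10L,
                             threshold = 1.1,
                             chain_seeds = dataset_seed * 1000 + seq_len(n_chains)) {
  spec <- if (inherits(preset, "simulation_spec")) preset
          else simulation_presets(preset)
  if (!length(moves) || !all(moves %in% 1:4))
    stop("moves must be a nonempty subset of 1:4")
  sim <- simulate_dataset(spec, seed = dataset_seed)
  expr <- center_data(sim$expr)
  p <- numeric(5)
  p[moves] <- (1 - 0.002) / length(moves)
  p[5] <- 0.002
  chains <- run_chains(expr, seeds = chain_seeds, n_iter = n_iter, thin = thin,
                       mode = "rank", fixed_params = true_params(spec),
                       move_cfg = move_config(n_cells(expr), p = p))
  report <- assess_convergence(chains, reference = sim$true_order,
                               threshold = threshold)
  final <- report$table[nrow(report$table), ]
  list(report = report,
       max_rhat = max(final$rhat_loglik, final$rhat_l1),
       dataset = sim, chains = chains)
}
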