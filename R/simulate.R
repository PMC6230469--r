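#' Benchmark simulation presets
#'
#' Three standard designs for assessing the order moves, each simulating 50
#' genes for 90 cells from per-gene Gaussian processes (see
#' [simulate_dataset()]):
#' \describe{
#'   \item{sim1}{three capture times with 30 cells each, low noise:
#'     `log(sigma_w) ~ N(0, 0.1)`, `log(l) ~ N(log 0.4, 0.1)`,
#'     `log(sigma_eps) ~ N(log 0.5, 0.1)` (second argument a variance).}
#'   \item{sim2}{as sim1 but two capture times, 30 cells then 60.}
#'   \item{sim3}{as sim1 but high noise: `log(sigma_eps) ~ N(0, 0.1)`.}
#' }
#' The study protocol attached as metadata: 16 datasets per design, 5
#' chains of 100,000 iterations each, thinning 10, hyperparameters fixed at
#' their generating values and rank-time mode, so that convergence reflects
#' the order moves alone.
#'
#' @param name one of `"sim1"`, `"sim2"`, `"sim3"`.
#' @return object of class `simulation_spec`.
#' @export
simulation_presets <- function(name = c("sim1", "sim2", "sim3")) {
  name <- match.arg(name)
  s <- sqrt(0.1)     # the generating laws state variances on the log scale
  spec <- list(name = name, n_genes = 50L, n_cells = 90L,
               blocks = switch(name, sim1 = c(30L, 30L, 30L),
                               sim2 = c(30L, 60L), sim3 = c(30L, 30L, 30L)),
               log_sw_mean = 0, log_sw_sd = s,
               log_l_mean = log(0.4), log_l_sd = s,
               log_eps_mean = if (name == "sim3") 0 else log(0.5),
               log_eps_sd = s,
               metadata = list(n_datasets = 16L, n_chains = 5L,
                               n_iter = 100000L, thin = 10L,
                               mode = "rank", fixed_params = TRUE))
  class(spec) <- "simulation_spec"
  spec
}

#' Custom simulation specification
#'
#' Same generative model as the presets with free dimensions and
#' hyperparameter laws; used to scale the designs down for quick checks.
#'
#' @param n_genes,n_cells dimensions of the simulated matrix.
#' @param blocks capture-time block sizes (must sum to `n_cells`).
#' @param log_sw_mean,log_sw_sd law of `log(sigma_w)` (mean and sd).
#' @param log_l_mean,log_l_sd law of `log(l)`.
#' @param log_eps_mean,log_eps_sd law of `log(sigma_eps)`.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes, n_cells, blocks = n_cells,
                            log_sw_mean = 0, log_sw_sd = sqrt(0.1),
                            log_l_mean = log(0.4), log_l_sd = sqrt(0.1),
                            log_eps_mean = log(0.5), log_eps_sd = sqrt(0.1)) {
  if (sum(blocks) != n_cells) stop("block sizes must sum to n_cells")
  if (any(c(log_sw_sd, log_l_sd, log_eps_sd) <= 0)) stop("sds must be positive")
  structure(list(name = "custom", n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), blocks = as.integer(blocks),
                 log_sw_mean = log_sw_mean, log_sw_sd = log_sw_sd,
                 log_l_mean = log_l_mean, log_l_sd = log_l_sd,
                 log_eps_mean = log_eps_mean, log_eps_sd = log_eps_sd,
                 metadata = list()),
            class = "simulation_spec")
}

#' Median generating hyperparameters of a simulation design
#'
#' The shared `gp_params` at which the sampler is fixed in the simulation
#' studies ("true values"): the medians of the per-gene laws, with
#' `sigma_eps2` taken from the noise law rather than from `V`.
#'
#' @param spec a `simulation_spec`.
#' @return a `gp_params` object.
#' @export
true_params <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  gp_params(sigma_w2 = exp(2 * spec$log_sw_mean),
            l = exp(spec$log_l_mean),
            sigma_eps2 = exp(2 * spec$log_eps_mean))
}

#' Simulate a GP trajectory dataset
#'
#' Draws `n_cells` input times uniformly on `[0, 1]`; for each gene draws
#' `(sigma_w, l, sigma_eps)` from the log-normal laws in `spec`, samples
#' the gene's trajectory from the noise-free squared-exponential GP at the
#' input times and adds iid `N(0, sigma_eps^2)` noise (together equivalent
#' to one draw from the full noisy kernel). Capture-time labels are assigned
#' by time-sorted blocks (earliest block first), and the cells are returned
#' in shuffled order together with the generating permutation.
#'
#' @param spec a `simulation_spec`.
#' @param seed integer seed.
#' @return list with `expr` (a `gporder_expr` with capture times),
#'   `true_order` (permutation sorting the shuffled cells by input time),
#'   `true_times` (per returned cell), `gene_params` (data frame of the
#'   per-gene draws), and `spec`.
#' @export
simulate_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  T <- spec$n_cells; ng <- spec$n_genes
  ts <- sort(stats::runif(T))
  sw <- exp(stats::rnorm(ng, spec$log_sw_mean, spec$log_sw_sd))
  l <- exp(stats::rnorm(ng, spec$log_l_mean, spec$log_l_sd))
  eps <- exp(stats::rnorm(ng, spec$log_eps_mean, spec$log_eps_sd))
  d2 <- outer(ts, ts, "-")^2
  Y <- matrix(0, ng, T)
  for (g in seq_len(ng)) {
    K <- sw[g]^2 * exp(-d2 / (2 * l[g]^2))
    L <- chol_jitter(K + diag(1e-10, T))
    Y[g, ] <- as.numeric(crossprod(L, stats::rnorm(T))) +
      eps[g] * stats::rnorm(T)
  }
  blocks <- rep(seq_along(spec$blocks), spec$blocks)   # label of each time rank
  sh <- sample.int(T)                                  # cell j has time rank sh[j]
  expr <- expression_matrix(Y[, sh, drop = FALSE],
                            gene_ids = paste0("g", seq_len(ng)),
                            cell_ids = sprintf("cell_%03d", seq_len(T)),
                            capture_times = blocks[sh])
  list(expr = expr,
       true_order = order(sh),
       true_times = ts[sh],
       gene_params = data.frame(sigma_w = sw, l = l, sigma_eps = eps),
       spec = spec)
}
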