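#' Sampler context: precomputed quantities for one dataset
#'
#' Bundles everything the Metropolis-Hastings steps need: the transposed
#' expression matrix, the pairwise Euclidean distances used by the geodesic
#' pseudotime mapping, the L1 pair-weight table of moves 2/3, the prior, and
#' -- when the hyperparameters are fixed and rank time is used -- a single
#' precomputed inverse covariance shared by all iterations.
#'
#' @param expr a `gporder_expr` object.
#' @param mode pseudotime mapping, `"geodesic"` (default) or `"rank"`.
#' @param move_cfg a `move_config`; default `move_config(T)`.
#' @param prior a `gp_prior`; default `prior_spec(expr$V)`. Ignored when
#'   `fixed_params` is given.
#' @param fixed_params optional `gp_params` to hold fixed throughout (used
#'   in the simulation studies, where the interest is in the order moves).
#' @param likelihood `"gp"` (default) or `"flat"`; the flat likelihood is a
#'   degenerate mode in which the data never enter, so the hyperparameter
#'   chain samples its prior -- used for validation.
#' @return object of class `sampler_context`.
#' @export
sampler_context <- function(expr, mode = c("geodesic", "rank"),
                            move_cfg = NULL, prior = NULL,
                            fixed_params = NULL,
                            likelihood = c("gp", "flat")) {
  stopifnot(inherits(expr, "gporder_expr"))
  mode <- match.arg(mode)
  likelihood <- match.arg(likelihood)
  T <- n_cells(expr); ng <- n_genes(expr)
  if (is.null(move_cfg)) move_cfg <- move_config(T)
  pdt <- pair_distance_table(expr, gamma = move_cfg$gamma,
                             alpha = move_cfg$alpha)
  fixed <- !is.null(fixed_params)
  if (fixed) stopifnot(inherits(fixed_params, "gp_params"))
  if (is.null(prior) && !fixed) prior <- prior_spec(expr$V)
  ctx <- list(expr = expr, Yt = t(expr$values), T = T, ng = ng,
              mode = mode, likelihood = likelihood,
              move_cfg = move_cfg, pdt = pdt,
              DE = if (mode == "geodesic") as.matrix(stats::dist(t(expr$values))) else NULL,
              tau_rank = rank_pseudotimes(T),
              prior = prior, fixed = fixed, fixed_params = fixed_params,
              fastpath = FALSE)
  if (fixed && mode == "rank" && likelihood == "gp") {
    K <- covariance_matrix(ctx$tau_rank, fixed_params)
    L <- chol_jitter(K, fixed_params)
    ctx$Kinv <- chol2inv(L)
    ctx$L <- L
    ctx$ll_const <- -0.5 * ng * T * log(2 * pi) - ng * sum(log(diag(L)))
    ctx$fastpath <- TRUE
  }
  class(ctx) <- "sampler_context"
  ctx
}

# pseudotimes of an ordering under the context's mapping
ctx_tau <- function(ctx, o) {
  if (ctx$mode == "rank") return(ctx$tau_rank)
  d <- ctx$DE[cbind(o[-ctx$T], o[-1L])]
  tt <- c(0, cumsum(d))
  if (tt[ctx$T] <= 0)
    stop("degenerate data: all consecutive cells identical")
  tt / tt[ctx$T]
}

# log-likelihood of (o, params); tau and/or the Cholesky factor L may be
# passed in when still valid (rank mode keeps tau fixed; an unchanged
# parameter set keeps L valid in rank mode)
ctx_loglik <- function(ctx, o, params, tau = NULL, L = NULL) {
  if (ctx$likelihood == "flat")
    return(list(ll = 0, tau = ctx$tau_rank, L = NULL))
  if (is.null(tau)) tau <- ctx_tau(ctx, o)
  Yo <- ctx$Yt[o, , drop = FALSE]
  if (ctx$fastpath) {
    quad <- sum(Yo * (ctx$Kinv %*% Yo))
    return(list(ll = ctx$ll_const - 0.5 * quad, tau = tau, L = ctx$L))
  }
  if (is.null(L)) {
    K <- covariance_matrix(tau, params)
    L <- chol_jitter(K, params)
  }
  Z <- backsolve(L, Yo, transpose = TRUE)
  list(ll = -0.5 * ctx$ng * ctx$T * log(2 * pi) - ctx$ng * sum(log(diag(L))) -
         0.5 * sum(Z^2),
       tau = tau, L = L)
}

#' Initialize a chain state
#'
#' The starting order is a uniformly random permutation of the cells within
#' each capture-time block, blocks concatenated in capture-time order; this
#' restriction speeds convergence without biasing the sampler and can be
#' disabled. Hyperparameters start at a draw from the prior (or at the fixed
#' values).
#'
#' @param ctx a `sampler_context`.
#' @param restrict keep starting orders within capture-time blocks
#'   (default `TRUE`; ignored when no capture times are present).
#' @param init_order optional explicit starting permutation.
#' @param init_prop_sd initial proposal standard deviations for
#'   `(log sigma_w2, log l)`.
#' @return object of class `chain_state`.
#' @export
init_chain <- function(ctx, restrict = TRUE, init_order = NULL,
                       init_prop_sd = c(0.1, 0.1)) {
  stopifnot(inherits(ctx, "sampler_context"))
  T <- ctx$T
  if (is.null(init_order)) {
    blocks <- if (restrict) capture_blocks(ctx$expr) else list(seq_len(T))
    o <- unlist(lapply(blocks, function(b) b[sample.int(length(b))]),
                use.names = FALSE)
  } else {
    check_permutation(init_order, T)
    o <- as.integer(init_order)
  }
  params <- if (ctx$fixed) ctx$fixed_params else sample_prior_params(ctx$prior)
  lp <- if (ctx$fixed) 0 else log_prior(params, ctx$prior)
  lik <- ctx_loglik(ctx, o, params)
  structure(list(o = o, params = params, tau = lik$tau, L = lik$L,
                 ll = lik$ll, lp = lp,
                 prop_sd = init_prop_sd,
                 iter = 0L, burned_in = FALSE,
                 prop_counts = integer(5), acc_counts = integer(5),
                 param_prop = 0L, param_acc = 0L,
                 param_prop_post = 0L, param_acc_post = 0L,
                 win_prop = 0L, win_acc = 0L),
            class = "chain_state")
}

#' One Metropolis-Hastings step on the ordering
#'
#' Proposes via the move mixture and accepts with probability
#' `min(1, exp(delta log-likelihood))`: the order prior is uniform and every
#' proposal kernel is symmetric, so only the likelihood ratio enters.
#'
#' @param state a `chain_state`.
#' @param ctx a `sampler_context`.
#' @return updated `chain_state`.
#' @export
mh_step_order <- function(state, ctx) {
  prop <- propose_order(state$o, ctx$move_cfg, ctx$pdt)
  mv <- prop$move
  state$prop_counts[mv] <- state$prop_counts[mv] + 1L
  reuse <- ctx$mode == "rank"
  cand <- ctx_loglik(ctx, prop$order, state$params,
                     tau = if (reuse) state$tau else NULL,
                     L = if (reuse) state$L else NULL)
  if (log(stats::runif(1)) < cand$ll - state$ll) {
    state$o <- prop$order
    state$tau <- cand$tau
    state$L <- cand$L
    state$ll <- cand$ll
    state$acc_counts[mv] <- state$acc_counts[mv] + 1L
  }
  state$iter <- state$iter + 1L
  state
}

#' One Metropolis-Hastings step on the GP hyperparameters
#'
#' Proposes `(log sigma_w2, log l)` jointly with independent Gaussian
#' increments and accepts the block with the likelihood-times-prior ratio.
#' Proposals with `sigma_w2 >= V` fall outside the prior support and are
#' rejected outright. A no-op when the context fixes the hyperparameters.
#'
#' @param state a `chain_state`.
#' @param ctx a `sampler_context`.
#' @return updated `chain_state`.
#' @export
mh_step_params <- function(state, ctx) {
  if (ctx$fixed) return(state)
  state$param_prop <- state$param_prop + 1L
  state$win_prop <- state$win_prop + 1L
  if (state$burned_in) state$param_prop_post <- state$param_prop_post + 1L
  lsw2 <- state$params$log_sigma_w2 + stats::rnorm(1, 0, state$prop_sd[1])
  ll_ <- state$params$log_l + stats::rnorm(1, 0, state$prop_sd[2])
  sw2 <- exp(lsw2)
  if (sw2 < ctx$prior$V && sw2 > 0 && is.finite(sw2)) {
    cand_params <- gp_params(sw2, exp(ll_), ctx$prior$V - sw2)
    lp_cand <- log_prior(cand_params, ctx$prior)
    cand <- ctx_loglik(ctx, state$o, cand_params, tau = state$tau, L = NULL)
    if (log(stats::runif(1)) < (cand$ll + lp_cand) - (state$ll + state$lp)) {
      state$params <- cand_params
      state$L <- cand$L
      state$ll <- cand$ll
      state$lp <- lp_cand
      state$param_acc <- state$param_acc + 1L
      state$win_acc <- state$win_acc + 1L
      if (state$burned_in) state$param_acc_post <- state$param_acc_post + 1L
    }
  }
  state
}

#' Adapt the hyperparameter proposal scales during burn-in
#'
#' Multiplies both proposal standard deviations by `up` when the windowed
#' acceptance rate exceeds 0.5 and by `down` when it falls below 0.45,
#' targeting acceptance rates between 0.45 and 0.5. Adaptation is only legal
#' during burn-in; afterwards the proposal is frozen to preserve ergodicity,
#' and calling this on a post-burn-in state is an error.
#'
#' @param state a `chain_state`.
#' @param window_acceptance acceptance rate observed in the last window.
#' @param up,down multiplicative factors (defaults 1.1 and 0.9).
#' @return updated `chain_state`.
#' @export
adapt_proposals <- function(state, window_acceptance, up = 1.1, down = 0.9) {
  if (isTRUE(state$burned_in))
    stop("proposal adaptation after burn-in would break ergodicity")
  if (window_acceptance > 0.5) state$prop_sd <- state$prop_sd * up
  else if (window_acceptance < 0.45) state$prop_sd <- state$prop_sd * down
  state
}

#' Run one MCMC chain
#'
#' Per iteration: one order proposal, then (unless the hyperparameters are
#' fixed) one joint hyperparameter proposal. During burn-in the
#' hyperparameter proposal scales adapt every `adapt_window` proposals.
#' Every `thin`-th state is stored. Fully deterministic given `seed`.
#'
#' @param expr a `gporder_expr` object.
#' @param n_iter number of iterations.
#' @param seed integer seed for this chain (required: chains are identified
#'   by their seed).
#' @param thin thinning factor (store every `thin`-th state), default 10.
#' @param burn_in number of burn-in iterations, default `floor(n_iter / 2)`.
#' @param mode,move_cfg,prior,fixed_params,likelihood passed to
#'   [sampler_context()].
#' @param restrict_start,init_order,init_prop_sd passed to [init_chain()].
#' @param adapt_window number of hyperparameter proposals per adaptation
#'   window (default 100).
#' @return object of class `gporder_chain`: thinned `orders` (one row per
#'   stored sample), traces `log_lik`, `log_sigma_w2`, `log_l`, move-wise
#'   and hyperparameter acceptance statistics, and run metadata.
#' @export
run_chain <- function(expr, n_iter, seed, thin = 10L,
                      burn_in = floor(n_iter / 2),
                      mode = c("geodesic", "rank"),
                      move_cfg = NULL, prior = NULL, fixed_params = NULL,
                      likelihood = c("gp", "flat"),
                      restrict_start = TRUE, init_order = NULL,
                      init_prop_sd = c(0.1, 0.1), adapt_window = 100L) {
  stopifnot(n_iter >= thin, thin >= 1)
  if (missing(seed)) stop("a chain seed is required")
  set.seed(seed)
  ctx <- sampler_context(expr, mode = mode, move_cfg = move_cfg,
                         prior = prior, fixed_params = fixed_params,
                         likelihood = likelihood)
  state <- init_chain(ctx, restrict = restrict_start,
                      init_order = init_order, init_prop_sd = init_prop_sd)
  n_samp <- floor(n_iter / thin)
  orders <- matrix(0L, n_samp, ctx$T)
  log_lik <- numeric(n_samp)
  lsw2 <- numeric(n_samp)
  ll_tr <- numeric(n_samp)
  k <- 0L
  i <- 0L
  sampling_params <- !ctx$fixed
  tryCatch(
    for (i in seq_len(n_iter)) {
      state <- mh_step_order(state, ctx)
      if (sampling_params) {
        state <- mh_step_params(state, ctx)
        if (!state$burned_in && state$win_prop >= adapt_window) {
          state <- adapt_proposals(state, state$win_acc / state$win_prop)
          state$win_prop <- 0L; state$win_acc <- 0L
        }
      }
      if (i >= burn_in) state$burned_in <- TRUE
      if (i %% thin == 0L) {
        k <- k + 1L
        orders[k, ] <- state$o
        log_lik[k] <- state$ll
        lsw2[k] <- state$params$log_sigma_w2
        ll_tr[k] <- state$params$log_l
      }
    },
    error = function(e)
      stop("iteration ", i, ": ", conditionMessage(e), call. = FALSE))
  structure(list(orders = orders, log_lik = log_lik,
                 log_sigma_w2 = lsw2, log_l = ll_tr,
                 iteration = thin * seq_len(n_samp),
                 T = ctx$T, n_iter = as.integer(n_iter),
                 thin = as.integer(thin), burn_in = as.integer(burn_in),
                 seed = seed, mode = ctx$mode,
                 acceptance = list(
                   moves = data.frame(move = 1:5,
                                      proposed = state$prop_counts,
                                      accepted = state$acc_counts),
                   params = c(proposed = state$param_prop,
                              accepted = state$param_acc),
                   params_post_burn_in = c(proposed = state$param_prop_post,
                                           accepted = state$param_acc_post),
                   prop_sd = state$prop_sd),
                 meta = list(move_cfg = ctx$move_cfg, prior = ctx$prior,
                             fixed_params = ctx$fixed_params,
                             likelihood = ctx$likelihood,
                             restrict_start = restrict_start,
                             cell_ids = ctx$expr$cell_ids)),
            class = "gporder_chain")
}

#' @export
print.gporder_chain <- function(x, ...) {
  cat(sprintf("MCMC chain: %d cells, %d iterations (thin %d, seed %s), mode %s\n",
              x$T, x$n_iter, x$thin, format(x$seed), x$mode))
  acc <- x$acceptance$moves
  ok <- acc$proposed > 0
  if (any(ok))
    cat("move acceptance:",
        paste(sprintf("m%d %.2f", acc$move[ok], acc$accepted[ok] / acc$proposed[ok]),
              collapse = ", "), "\n")
  if (x$acceptance$params["proposed"] > 0)
    cat(sprintf("hyperparameter acceptance: %.2f (post burn-in %.2f)\n",
                x$acceptance$params["accepted"] / x$acceptance$params["proposed"],
                x$acceptance$params_post_burn_in["accepted"] /
                  max(1, x$acceptance$params_post_burn_in["proposed"])))
  invisible(x)
}

#' Run several independently seeded chains
#'
#' @param expr a `gporder_expr` object.
#' @param seeds vector of distinct integer seeds, one per chain.
#' @param ... further arguments to [run_chain()].
#' @return list of `gporder_chain` objects (class `gporder_chains`).
#' @export
run_chains <- function(expr, seeds, ...) {
  if (anyDuplicated(seeds)) stop("chain seeds must be distinct")
  out <- lapply(seeds, function(s) run_chain(expr, seed = s, ...))
  class(out) <- "gporder_chains"
  out
}

# draws x T matrix of cell positions: row k gives, for each cell, its
# position under the k-th stored ordering
orders_to_positions <- function(orders) {
  n <- nrow(orders); T <- ncol(orders)
  P <- matrix(0L, n, T)
  idx <- seq_len(T)
  for (k in seq_len(n)) P[k, orders[k, ]] <- idx
  P
}
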