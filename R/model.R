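#' Gaussian-process hyperparameters
#'
#' The trajectory of every gene is modelled by one shared zero-mean Gaussian
#' process with squared-exponential covariance
#' \deqn{\Sigma_{ij} = \sigma_w^2 \exp(-(\tau_j - \tau_i)^2 / (2 l^2)) +
#'   \delta_{ij}\,\sigma_\epsilon^2,}
#' where `sigma_w2` is the signal variance, `l` the length scale and
#' `sigma_eps2` the iid measurement-noise variance.
#'
#' @param sigma_w2 signal variance, > 0.
#' @param l length scale, > 0.
#' @param sigma_eps2 noise variance, > 0.
#' @return object of class `gp_params`.
#' @export
gp_params <- function(sigma_w2, l, sigma_eps2) {
  if (!all(is.finite(c(sigma_w2, l, sigma_eps2))))
    stop("non-finite GP hyperparameters")
  if (sigma_w2 <= 0 || l <= 0 || sigma_eps2 <= 0)
    stop("GP hyperparameters must be strictly positive")
  structure(list(sigma_w2 = sigma_w2, l = l, sigma_eps2 = sigma_eps2,
                 log_sigma_w2 = log(sigma_w2), log_l = log(l)),
            class = "gp_params")
}

#' @describeIn gp_params construct hyperparameters from the signal variance
#'   and the total variance `V`, setting `sigma_eps2 = V - sigma_w2`
#'   (requires `sigma_w2 < V`).
#' @param V total sample variance of the expression matrix.
#' @export
gp_params_from_V <- function(sigma_w2, l, V) {
  if (sigma_w2 >= V)
    stop("sigma_w2 must be strictly smaller than the total variance V")
  gp_params(sigma_w2, l, V - sigma_w2)
}

#' Squared-exponential covariance matrix
#'
#' @param tau numeric vector of pseudotimes.
#' @param params a `gp_params` object.
#' @return T x T symmetric positive-definite covariance matrix.
#' @export
covariance_matrix <- function(tau, params) {
  if (!is.numeric(tau) || any(!is.finite(tau)))
    stop("pseudotimes must be finite numeric values")
  stopifnot(inherits(params, "gp_params"))
  d <- outer(tau, tau, "-")
  params$sigma_w2 * exp(-d^2 / (2 * params$l^2)) +
    diag(params$sigma_eps2, length(tau))
}

# Cholesky with escalating diagonal jitter. Starts at 1e-10 * trace/T and
# multiplies by 10 up to 1e-6 * trace/T before giving up.
chol_jitter <- function(K, params = NULL) {
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(L)) return(L)
  base <- mean(diag(K))
  jit <- 1e-10 * base
  while (jit <= 1e-6 * base) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- jit * 10
  }
  extra <- if (is.null(params)) "" else
    sprintf(" (sigma_w2 = %.4g, l = %.4g, sigma_eps2 = %.4g)",
            params$sigma_w2, params$l, params$sigma_eps2)
  stop("covariance matrix could not be factorized even with jitter", extra)
}

#' Rank-time pseudotimes
#'
#' Equidistant pseudotimes `(i - 0.5) / T` for positions `i = 1..T`.
#'
#' @param T number of cells (>= 1).
#' @return numeric vector of length `T`.
#' @export
rank_pseudotimes <- function(T) {
  stopifnot(T >= 1)
  (seq_len(T) - 0.5) / T
}

#' Geodesic pseudotimes of an ordering
#'
#' Maps an ordering to pseudotimes by accumulating the Euclidean distances
#' between consecutively ranked cells (an Isomap-style approximation of the
#' geodesic distance from the first cell), then rescaling to `[0, 1]`.
#' Cells that are close in expression end up close in pseudotime, so the
#' local time scale adapts to the speed of change along the trajectory.
#'
#' @param expr a `gporder_expr` object.
#' @param o integer permutation of the cells (`o[j]` = cell at position `j`).
#' @return nondecreasing pseudotime vector with `tau[1] = 0`, `max(tau) = 1`.
#' @export
geodesic_pseudotimes <- function(expr, o) {
  stopifnot(inherits(expr, "gporder_expr"))
  T <- n_cells(expr)
  check_permutation(o, T)
  Y <- expr$values
  d <- sqrt(colSums((Y[, o[-1], drop = FALSE] - Y[, o[-T], drop = FALSE])^2))
  tt <- c(0, cumsum(unname(d)))
  if (tt[T] <= 0)
    stop("degenerate data: all consecutive cells identical, geodesic pseudotimes undefined")
  tt / tt[T]
}

check_permutation <- function(o, T) {
  if (length(o) != T || !all(sort.int(as.integer(o)) == seq_len(T)))
    stop("not a permutation of 1..", T)
  invisible(TRUE)
}

#' GP marginal log-likelihood of an ordering
#'
#' Sum over genes of the zero-mean multivariate-normal log-density of the
#' reordered expression vector under the shared covariance evaluated at the
#' pseudotimes of the ordering. One Cholesky factorization is shared across
#' all genes.
#'
#' @param expr a `gporder_expr` object.
#' @param o integer permutation of the cells.
#' @param params a `gp_params` object.
#' @param mode `"geodesic"` (default) or `"rank"` pseudotime mapping.
#' @return log-likelihood value.
#' @export
gp_log_likelihood <- function(expr, o, params, mode = c("geodesic", "rank")) {
  mode <- match.arg(mode)
  T <- n_cells(expr)
  check_permutation(o, T)
  tau <- if (mode == "geodesic") geodesic_pseudotimes(expr, o)
         else rank_pseudotimes(T)
  K <- covariance_matrix(tau, params)
  L <- chol_jitter(K, params)
  Yo <- t(expr$values[, o, drop = FALSE])      # T x n_g
  Z <- backsolve(L, Yo, transpose = TRUE)
  ng <- n_genes(expr)
  -0.5 * ng * T * log(2 * pi) - ng * sum(log(diag(L))) - 0.5 * sum(Z^2)
}

#' Prior specification for the GP hyperparameters
#'
#' Informative log-normal priors keep the noise variance low relative to the
#' signal: the prior on the log signal variance is centered at
#' `log(0.9 * V)` so that, with `sigma_eps2 = V - sigma_w2`, roughly 90% of
#' the total variance is attributed to the trajectory. The length-scale
#' prior is tight (`sd = 0.1` on the log scale by default) because a vague
#' length-scale prior lets the GP overfit single-cell noise. The prior over
#' orderings is uniform on all permutations and therefore drops out of
#' acceptance ratios.
#'
#' @param V total sample variance of the (centered) expression matrix.
#' @param log_signal_mean,log_signal_sd mean and sd of the normal prior on
#'   the log signal parameter (see `signal_scale`).
#' @param log_l_mean,log_l_sd mean and sd of the normal prior on `log(l)`.
#' @param signal_scale whether the signal prior is placed on the log
#'   variance `log(sigma_w2)` (default) or on the log standard deviation
#'   `log(sigma_w)`; both are exposed because either reading keeps the
#'   noise-to-signal ratio low.
#' @return object of class `gp_prior`.
#' @export
prior_spec <- function(V,
                       log_signal_mean = log(0.9 * V),
                       log_signal_sd = 0.1,
                       log_l_mean = log(0.5),
                       log_l_sd = 0.1,
                       signal_scale = c("variance", "sd")) {
  signal_scale <- match.arg(signal_scale)
  if (!is.finite(V) || V <= 0) stop("V must be a positive number")
  if (log_signal_sd <= 0 || log_l_sd <= 0) stop("prior sds must be positive")
  if (signal_scale == "sd") {     # log sigma_w ~ N(m, s) => log sigma_w2 ~ N(2m, 2s)
    log_signal_mean <- 2 * log_signal_mean
    log_signal_sd <- 2 * log_signal_sd
  }
  structure(list(V = V, lsw2_mean = log_signal_mean, lsw2_sd = log_signal_sd,
                 ll_mean = log_l_mean, ll_sd = log_l_sd),
            class = "gp_prior")
}

#' Log prior density of the GP hyperparameters
#'
#' Sum of the two normal log-densities on `log(sigma_w2)` and `log(l)`.
#' Outside the support (`sigma_w2 >= V`, which would make the implied noise
#' variance nonpositive) the value is `-Inf` rather than an error, so that
#' Metropolis-Hastings proposals falling outside are simply rejected.
#'
#' @param params a `gp_params` object.
#' @param prior a `gp_prior` object.
#' @return log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, prior) {
  stopifnot(inherits(params, "gp_params"), inherits(prior, "gp_prior"))
  if (params$sigma_w2 >= prior$V) return(-Inf)
  stats::dnorm(params$log_sigma_w2, prior$lsw2_mean, prior$lsw2_sd, log = TRUE) +
    stats::dnorm(params$log_l, prior$ll_mean, prior$ll_sd, log = TRUE)
}

#' Draw GP hyperparameters from the prior
#'
#' Draws `log(sigma_w2)` and `log(l)` from their normal priors, redrawing
#' (up to `max_tries` times) until the implied noise variance
#' `V - sigma_w2` is strictly positive.
#'
#' @param prior a `gp_prior` object.
#' @param max_tries retry budget for the support rejection.
#' @return a `gp_params` object with `sigma_eps2 = V - sigma_w2`.
#' @export
sample_prior_params <- function(prior, max_tries = 1000L) {
  stopifnot(inherits(prior, "gp_prior"))
  for (i in seq_len(max_tries)) {
    lsw2 <- stats::rnorm(1, prior$lsw2_mean, prior$lsw2_sd)
    ll <- stats::rnorm(1, prior$ll_mean, prior$ll_sd)
    if (exp(lsw2) < prior$V)
      return(gp_params(exp(lsw2), exp(ll), prior$V - exp(lsw2)))
  }
  stop("prior is inconsistent with total variance V: could not draw sigma_w2 < V in ",
       max_tries, " tries")
}
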