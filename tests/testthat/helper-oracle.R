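# shared fixtures and independent oracles, built in code at test time

# all permutations of 1..n as rows (recursive construction)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- c(seq_len(n)[-k])
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# small random expression matrix
rand_expr <- function(n_g, T, seed, capture_times = NULL) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_g * T), n_g, T),
                    capture_times = capture_times)
}

# naive per-gene multivariate-normal log-likelihood via solve()/determinant(),
# independent of the Cholesky-based implementation path
mvn_ll_oracle <- function(expr, o, params, mode = "geodesic") {
  T <- n_cells(expr)
  tau <- if (mode == "geodesic") geodesic_pseudotimes(expr, o)
         else rank_pseudotimes(T)
  S <- params$sigma_w2 * exp(-outer(tau, tau, "-")^2 / (2 * params$l^2)) +
    diag(params$sigma_eps2, T)
  Si <- solve(S)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  sum(apply(expr$values[, o, drop = FALSE], 1, function(y)
    -0.5 * (T * log(2 * pi) + ld + drop(t(y) %*% Si %*% y))))
}

# exact posterior over all T! orderings at fixed hyperparameters
enum_posterior <- function(expr, params, mode = "geodesic") {
  P <- all_perms(n_cells(expr))
  ll <- apply(P, 1, function(o) gp_log_likelihood(expr, o, params, mode = mode))
  w <- exp(ll - max(ll))
  list(perms = P, prob = w / sum(w))
}

# integer key of a permutation of 1..n (mixed-radix; unique for small n)
perm_key <- function(o, n) as.integer(sum((o - 1) * n^(seq_along(o) - 1)))

# independent plain-loop transcription of the corrected potential scale
# reduction factor (between/within variance ratio with the method-of-moments
# degrees-of-freedom adjustment (d+3)/(d+1))
psrf_oracle <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  xbar <- sapply(chains, mean)
  s2 <- sapply(chains, var)
  W <- mean(s2); B <- n * var(xbar); mu <- mean(xbar)
  Vhat <- (n - 1) / n * W + (1 + 1 / m) / n * B
  var_w <- var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (cov(s2, xbar^2) - 2 * mu * cov(s2, xbar))
  var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
              2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
  d <- 2 * Vhat^2 / var_V
  sqrt((d + 3) / (d + 1) * Vhat / W)
}
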