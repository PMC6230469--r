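#' Resolve the reversal symmetry of sampled orderings
#'
#' The posterior over orderings is symmetric under full reversal, so chains
#' visit an ordering and its mirror image with equal probability. Before
#' summarizing, every stored order whose cell positions correlate
#' negatively (Spearman) with an anchor -- the capture times, or a marker
#' gene's expression -- is replaced by its reversal. Draws with exactly zero
#' correlation are left unchanged.
#'
#' @param samples a `gporder_chain`, or a list of them (resolved per chain).
#' @param anchor numeric vector over cells, e.g. capture times.
#' @return object(s) of the same shape with reversals resolved.
#' @export
resolve_reversals <- function(samples, anchor) {
  if (inherits(samples, "gporder_chain"))
    return(resolve_one(samples, anchor))
  out <- lapply(samples, resolve_one, anchor = anchor)
  class(out) <- class(samples)
  out
}

resolve_one <- function(chain, anchor) {
  stopifnot(inherits(chain, "gporder_chain"))
  T <- chain$T
  if (length(anchor) != T) stop("anchor must have one value per cell")
  ra <- rank(anchor)
  if (stats::sd(ra) == 0)
    stop("anchor is constant; use a marker gene's expression as anchor")
  rac <- ra - mean(ra)
  P <- orders_to_positions(chain$orders)
  # positions are their own ranks, so the sign of the Spearman correlation
  # is the sign of the centered cross-product
  s <- as.numeric(P %*% rac)
  flip <- s < 0
  if (any(flip))
    chain$orders[flip, ] <- chain$orders[flip, ncol(P):1, drop = FALSE]
  chain$reversals_resolved <- sum(flip)
  chain
}

# pooled post-burn-in orders across one chain or a list of chains
pool_orders <- function(samples, discard = 0.5) {
  if (inherits(samples, "gporder_chain")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(ch) {
    n <- nrow(ch$orders)
    keep <- (floor(n * discard) + 1):n
    ch$orders[keep, , drop = FALSE]
  }))
}

#' Posterior summary of cell pseudotimes and positions
#'
#' For every pooled post-burn-in draw the pseudotimes are recomputed (by
#' the geodesic mapping, or rank time), giving each cell one pseudotime per
#' draw. Reported are the per-cell mean and standard deviation of
#' pseudotime, the cell x rank position-frequency matrix (each row sums to
#' 1), and a modal ordering defined as the cells sorted by mean pseudotime
#' (ties broken by cell index). Apply [resolve_reversals()] first, or the
#' mirrored draws wash the summaries out.
#'
#' @param samples a `gporder_chain` or list of chains.
#' @param expr the `gporder_expr` the chains were run on.
#' @param mode pseudotime mapping used for the summary, `"geodesic"`
#'   (default) or `"rank"`.
#' @param discard fraction of each chain discarded as burn-in (default 0.5).
#' @return object of class `posterior_summary` with elements `percell`
#'   (data frame: `cell_id`, `mean_pseudotime`, `sd_pseudotime`),
#'   `position_freq`, `modal_order` and `n_draws`.
#' @export
summarize_posterior <- function(samples, expr, mode = c("geodesic", "rank"),
                                discard = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "gporder_expr"))
  orders <- pool_orders(samples, discard)
  n <- nrow(orders); T <- ncol(orders)
  if (n < 1) stop("no stored draws to summarize")
  if (T != n_cells(expr)) stop("chains and expression matrix disagree on cell count")
  DE <- if (mode == "geodesic") as.matrix(stats::dist(t(expr$values))) else NULL
  tau_rank <- rank_pseudotimes(T)
  s1 <- numeric(T); s2 <- numeric(T)
  freq <- matrix(0, T, T)
  pt <- numeric(T)
  for (k in seq_len(n)) {
    o <- orders[k, ]
    if (mode == "geodesic") {
      tt <- c(0, cumsum(DE[cbind(o[-T], o[-1L])]))
      tau <- tt / tt[T]
    } else tau <- tau_rank
    pt[o] <- tau
    s1 <- s1 + pt
    s2 <- s2 + pt^2
    freq[cbind(o, seq_len(T))] <- freq[cbind(o, seq_len(T))] + 1
  }
  mean_pt <- s1 / n
  sd_pt <- sqrt(pmax(0, s2 / n - mean_pt^2))
  freq <- freq / n
  rownames(freq) <- expr$cell_ids
  colnames(freq) <- paste0("rank_", seq_len(T))
  structure(list(percell = data.frame(cell_id = expr$cell_ids,
                                      mean_pseudotime = mean_pt,
                                      sd_pseudotime = sd_pt,
                                      stringsAsFactors = FALSE),
                 position_freq = freq,
                 modal_order = order(mean_pt),
                 n_draws = n, mode = mode),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior summary over %d draws (%s pseudotime)\n",
              x$n_draws, x$mode))
  print(utils::head(x$percell), row.names = FALSE, digits = 4)
  if (nrow(x$percell) > 6) cat("...", nrow(x$percell) - 6, "more cells\n")
  invisible(x)
}

#' Classical MDS embedding of sampled position vectors
#'
#' Embeds the draws (as T-dimensional cell-position vectors) into two
#' dimensions by classical multidimensional scaling of their Euclidean
#' distance matrix. Areas of high point density correspond to local modes
#' of the posterior over orderings.
#'
#' @param samples a `gporder_chain` or list of chains.
#' @param n_draws maximum number of draws embedded (evenly subsampled,
#'   default 500); distance matrices grow quadratically in this number.
#' @param discard fraction of each chain discarded as burn-in.
#' @return object of class `mds_positions`: `points` (draws x 2, or x 1
#'   with a warning if the configuration is rank-deficient), eigenvalues
#'   `eig`, and the draw indices used.
#' @export
mds_positions <- function(samples, n_draws = 500, discard = 0.5) {
  orders <- pool_orders(samples, discard)
  n <- nrow(orders)
  if (n < 3) stop("need at least 3 draws for an embedding")
  idx <- if (n > n_draws) unique(round(seq(1, n, length.out = n_draws))) else seq_len(n)
  P <- orders_to_positions(orders[idx, , drop = FALSE])
  mds <- stats::cmdscale(stats::dist(P), k = 2, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < 2) {
    warning("position configuration is rank-deficient; returning 1D embedding")
  }
  structure(list(points = pts, eig = mds$eig, draw_index = idx),
            class = "mds_positions")
}

#' Mean expression of a gene set along pseudotime
#'
#' Per-cell average expression of the listed genes (e.g. an antiviral
#' response signature), paired with the cell's posterior mean pseudotime --
#' a one-line check that the inferred ordering tracks a known biological
#' program.
#'
#' @param expr a `gporder_expr` object.
#' @param gene_set character vector of gene identifiers; all must be
#'   present in `expr`.
#' @param summary a `posterior_summary` for the same cells.
#' @return data frame with `cell_id`, `mean_pseudotime`, `score`.
#' @export
gene_set_score <- function(expr, gene_set, summary) {
  stopifnot(inherits(expr, "gporder_expr"),
            inherits(summary, "posterior_summary"))
  gene_set <- unique(as.character(gene_set))
  missing <- setdiff(gene_set, expr$gene_ids)
  if (length(missing))
    stop("genes not in the expression matrix: ", paste(missing, collapse = ", "))
  score <- colMeans(expr$values[gene_set, , drop = FALSE])
  data.frame(cell_id = expr$cell_ids,
             mean_pseudotime = summary$percell$mean_pseudotime,
             score = as.numeric(score),
             stringsAsFactors = FALSE)
}
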