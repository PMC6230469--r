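#' ANOVA gene filter across capture times
#'
#' One-way ANOVA F-test per gene for differences in mean expression between
#' capture-time groups; genes are ranked by p-value and the most
#' differential ones kept. This selects the genes most informative about
#' progression when capture times are available.
#'
#' @param expr a `gporder_expr` with at least two capture times and at
#'   least two cells per capture time.
#' @param n_keep number of genes to retain (default 100, capped at the
#'   number of genes).
#' @param p_threshold optional p-value cutoff used instead of `n_keep`.
#' @return filtered `gporder_expr` (total variance `V` recomputed), with
#'   the per-gene table in attribute `"anova"`.
#' @export
anova_gene_filter <- function(expr, n_keep = 100L, p_threshold = NULL) {
  stopifnot(inherits(expr, "gporder_expr"))
  ct <- expr$capture_times
  if (is.null(ct) || length(unique(ct)) < 2)
    stop("ANOVA filter needs >= 2 capture times; use mean_variance_filter() instead")
  g <- factor(ct)
  if (any(table(g) < 2)) stop("every capture time needs at least 2 cells")
  Y <- expr$values
  N <- ncol(Y); k <- nlevels(g)
  counts <- as.numeric(table(g))
  # vectorized one-way ANOVA: between / within mean squares per gene
  gm <- t(vapply(levels(g), function(lv) rowMeans(Y[, g == lv, drop = FALSE]),
                 numeric(nrow(Y))))                       # k x n_g group means
  grand <- rowMeans(Y)
  ssb <- colSums(counts * (gm - matrix(grand, k, nrow(Y), byrow = TRUE))^2)
  ssw <- rowSums((Y - t(gm[as.integer(g), , drop = FALSE]))^2)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(F, k - 1, N - k, lower.tail = FALSE)
  tab <- data.frame(gene_id = expr$gene_ids, F = F, p = p,
                    stringsAsFactors = FALSE)
  keep <- if (!is.null(p_threshold)) which(p < p_threshold)
          else order(p)[seq_len(min(n_keep, nrow(Y)))]
  keep <- sort(keep)
  if (!length(keep)) stop("no gene passes the ANOVA filter")
  out <- expression_matrix(Y[keep, , drop = FALSE],
                           gene_ids = expr$gene_ids[keep],
                           cell_ids = expr$cell_ids,
                           capture_times = ct)
  attr(out, "anova") <- tab
  out
}

#' Mean/variance gene filter
#'
#' Without capture times, keeps genes that are high in both mean expression
#' and variance: genes are scored by the worse of their two top-down ranks
#' (by mean and by variance), which is equivalent to intersecting top
#' quantiles by both criteria and widening until `n_keep` genes qualify.
#'
#' @param expr a `gporder_expr` object.
#' @param n_keep number of genes to retain.
#' @return filtered `gporder_expr` with `V` recomputed.
#' @export
mean_variance_filter <- function(expr, n_keep) {
  stopifnot(inherits(expr, "gporder_expr"))
  Y <- expr$values
  n_keep <- min(n_keep, nrow(Y))
  rm_ <- rank(-rowMeans(Y), ties.method = "first")
  rv_ <- rank(-apply(Y, 1, stats::var), ties.method = "first")
  score <- pmax(rm_, rv_)
  keep <- sort(order(score, rm_)[seq_len(n_keep)])
  expression_matrix(Y[keep, , drop = FALSE],
                    gene_ids = expr$gene_ids[keep],
                    cell_ids = expr$cell_ids,
                    capture_times = expr$capture_times)
}
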