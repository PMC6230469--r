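#' Mini-cluster approximation for large datasets
#'
#' Clusters cells into many very small clusters by k-means -- separately
#' within each capture time, so no cluster straddles capture times -- and
#' replaces the cells by the cluster centroids. The sampler then runs over
#' orderings of the centroids (a much smaller permutation space), and each
#' cell inherits the posterior pseudotime of its centroid via
#' [expand_pseudotimes()]. The recommended cluster count per capture time
#' is 1/8 of the cells at that capture time, floored at `min_clusters`.
#'
#' @param expr a `gporder_expr` object (cells need not be pre-sorted; the
#'   centroid matrix is assembled in capture-time order).
#' @param fraction clusters per cell within a capture time (default 1/8).
#' @param min_clusters minimum clusters per capture time (default 5).
#' @param seed seed for the k-means restarts (default 1).
#' @param nstart k-means restarts (default 10).
#' @return object of class `minicluster_map`: `centroids` (a
#'   `gporder_expr` of centroid profiles with inherited capture times and
#'   recomputed total variance `V`), `assignment` (per original cell, its
#'   centroid index), `cell_ids`, and `k_per_block`. When a block needs as
#'   many clusters as it has cells, each cell becomes its own centroid and
#'   downstream results coincide with the exact method.
#' @export
build_miniclusters <- function(expr, fraction = 1 / 8, min_clusters = 5L,
                               seed = 1L, nstart = 10L) {
  stopifnot(inherits(expr, "gporder_expr"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  blocks <- capture_blocks(expr)
  if (any(lengths(blocks) == 0)) stop("empty capture-time block")
  set.seed(seed)
  cent_cols <- list(); cent_ids <- character(0); cent_ct <- c()
  assignment <- integer(n_cells(expr))
  k_per_block <- integer(length(blocks))
  offset <- 0L
  for (bi in seq_along(blocks)) {
    cells <- blocks[[bi]]
    n_t <- length(cells)
    k <- max(min_clusters, round(n_t * fraction))
    ct_label <- if (is.null(expr$capture_times)) NA else expr$capture_times[cells[1]]
    if (k >= n_t) {                      # one cell per cluster: exact method
      k <- n_t
      cent_cols[[bi]] <- expr$values[, cells, drop = FALSE]
      assignment[cells] <- offset + seq_len(n_t)
      ids <- expr$cell_ids[cells]
    } else {
      km <- stats::kmeans(t(expr$values[, cells, drop = FALSE]),
                          centers = k, nstart = nstart)
      cent_cols[[bi]] <- t(km$centers)
      assignment[cells] <- offset + km$cluster
      ids <- paste0("mc", bi, "_", seq_len(k))
    }
    cent_ids <- c(cent_ids, ids)
    cent_ct <- c(cent_ct, rep(ct_label, k))
    k_per_block[bi] <- k
    offset <- offset + k
  }
  values <- do.call(cbind, cent_cols)
  colnames(values) <- cent_ids
  centroids <- expression_matrix(values, gene_ids = expr$gene_ids,
                                 cell_ids = cent_ids,
                                 capture_times = if (is.null(expr$capture_times)) NULL else cent_ct)
  structure(list(centroids = centroids, assignment = assignment,
                 cell_ids = expr$cell_ids,
                 capture_times = expr$capture_times,
                 k_per_block = k_per_block),
            class = "minicluster_map")
}

#' @export
print.minicluster_map <- function(x, ...) {
  cat(sprintf("mini-cluster map: %d cells -> %d centroids (%s per block)\n",
              length(x$assignment), n_cells(x$centroids),
              paste(x$k_per_block, collapse = ", ")))
  invisible(x)
}

#' Expand centroid pseudotimes back to the member cells
#'
#' Every original cell receives the posterior mean and standard deviation
#' of the pseudotime of its centroid, and the centroid's position
#' distribution.
#'
#' @param map a `minicluster_map`.
#' @param centroid_summary a `posterior_summary` computed on the centroid
#'   chains (indexed by centroid).
#' @return list of class `expanded_summary`: `percell` data frame
#'   (`cell_id`, `centroid_id`, `mean_pseudotime`, `sd_pseudotime`) and the
#'   expanded `position_freq` (cells x centroid ranks).
#' @export
expand_pseudotimes <- function(map, centroid_summary) {
  stopifnot(inherits(map, "minicluster_map"),
            inherits(centroid_summary, "posterior_summary"))
  k <- n_cells(map$centroids)
  if (nrow(centroid_summary$percell) != k)
    stop("summary is not indexed by the centroids of this map")
  a <- map$assignment
  if (any(a < 1 | a > k) || anyNA(a))
    stop("unmapped cell in mini-cluster assignment")
  percell <- data.frame(cell_id = map$cell_ids,
                        centroid_id = centroid_summary$percell$cell_id[a],
                        mean_pseudotime = centroid_summary$percell$mean_pseudotime[a],
                        sd_pseudotime = centroid_summary$percell$sd_pseudotime[a],
                        stringsAsFactors = FALSE)
  pf <- centroid_summary$position_freq[a, , drop = FALSE]
  rownames(pf) <- map$cell_ids
  structure(list(percell = percell, position_freq = pf),
            class = "expanded_summary")
}

#' Write a mini-cluster map as delimited text
#'
#' One row per cell: `cell_id`, `capture_time`, `centroid_id`.
#'
#' @param map a `minicluster_map`.
#' @param path output file.
#' @export
write_minicluster_map <- function(map, path) {
  stopifnot(inherits(map, "minicluster_map"))
  utils::write.csv(data.frame(
    cell_id = map$cell_ids,
    capture_time = if (is.null(map$capture_times)) NA else map$capture_times,
    centroid_id = map$centroids$cell_ids[map$assignment],
    stringsAsFactors = FALSE), path, row.names = FALSE)
  invisible(path)
}
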