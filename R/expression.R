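#' Expression matrix container
#'
#' Bundles a log-scale expression matrix (genes in rows, cells in columns)
#' with gene and cell identifiers, optional per-cell capture times, and the
#' total sample variance `V` taken across all entries. `V` is the quantity
#' that ties the signal and noise variances of the trajectory model together
#' (the noise variance is `V - sigma_w2`), so it is recomputed whenever the
#' matrix changes.
#'
#' @param values numeric matrix, genes x cells, log scale, no missing values.
#' @param gene_ids character vector of gene identifiers (defaults to
#'   rownames of `values`, or `g1..gn`).
#' @param cell_ids character vector of cell identifiers (defaults to
#'   colnames of `values`, or `c1..cT`).
#' @param capture_times optional per-cell capture-time labels or values,
#'   coercible to numeric ranks; length must equal the number of cells.
#' @return an object of class `gporder_expr` with fields `values`,
#'   `gene_ids`, `cell_ids`, `capture_times` and `V`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                              capture_times = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values contain missing or non-finite entries")
  n_g <- nrow(values); T <- ncol(values)
  if (n_g < 1L) stop("need at least one gene")
  if (T < 2L) stop("need at least two cells")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_g))
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(T))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != n_g) stop("gene_ids length does not match matrix")
  if (length(cell_ids) != T) stop("cell_ids length does not match matrix")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (!is.null(capture_times)) {
    if (length(capture_times) != T)
      stop("capture_times length does not match number of cells")
  }
  rownames(values) <- gene_ids; colnames(values) <- cell_ids
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 capture_times = capture_times,
                 V = stats::var(as.vector(values))),
            class = "gporder_expr")
}

#' @export
print.gporder_expr <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d cells (V = %.4g)\n",
              nrow(x$values), ncol(x$values), x$V))
  if (!is.null(x$capture_times)) {
    tab <- table(x$capture_times)
    cat("capture times:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells / genes in an expression matrix
#' @param expr a `gporder_expr` object.
#' @return integer count.
#' @export
n_cells <- function(expr) ncol(expr$values)

#' @rdname n_cells
#' @export
n_genes <- function(expr) nrow(expr$values)

#' Attach capture times to an expression matrix
#'
#' @param expr a `gporder_expr` object.
#' @param cell_id,capture_time vectors pairing each cell identifier with its
#'   capture-time label; all cells of `expr` must be covered.
#' @return `expr` with `capture_times` filled in (matched by cell id).
#' @export
attach_capture_times <- function(expr, cell_id, capture_time) {
  idx <- match(expr$cell_ids, as.character(cell_id))
  if (anyNA(idx)) {
    missing <- expr$cell_ids[is.na(idx)]
    stop("no capture time for cells: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  expr$capture_times <- capture_time[idx]
  expr
}

#' Grand-mean centering
#'
#' Subtracts the single overall mean across all genes and cells from every
#' entry, matching the zero-mean assumption of the trajectory model. The
#' total variance `V` is recomputed (it is unchanged in exact arithmetic).
#'
#' @param expr a `gporder_expr` object.
#' @return centered `gporder_expr`.
#' @export
center_data <- function(expr) {
  stopifnot(inherits(expr, "gporder_expr"))
  expr$values <- expr$values - mean(expr$values)
  expr$V <- stats::var(as.vector(expr$values))
  expr
}

# capture-time blocks as a list of cell-index vectors, in increasing
# capture-time order; a single block when no capture times are present
capture_blocks <- function(expr) {
  ct <- expr$capture_times
  T <- n_cells(expr)
  if (is.null(ct)) return(list(seq_len(T)))
  lev <- sort(unique(ct))
  lapply(lev, function(l) which(ct == l))
}
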