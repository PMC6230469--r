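#' Read an expression matrix from delimited text
#'
#' Expected layout: a header row of cell identifiers, one row per gene with
#' the gene identifier in the first column. The separator is taken from the
#' file extension (`.csv` vs `.tsv`/`.txt`) or sniffed from the header line.
#'
#' @param path input file.
#' @param sep field separator; `NULL` (default) to autodetect.
#' @return a `gporder_expr` (without capture times).
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\""),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(df) < 3) stop(path, ": expected gene ids plus at least 2 cell columns")
  gene_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    stop(path, ": non-numeric expression values in column ", bad)
  }
  expression_matrix(vals, gene_ids = gene_ids, cell_ids = colnames(df)[-1])
}

sniff_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab")) return("\t")
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Write an expression matrix as delimited text
#'
#' @param expr a `gporder_expr`.
#' @param path output file.
#' @param sep field separator (default `","`).
#' @export
write_expression <- function(expr, path, sep = ",") {
  stopifnot(inherits(expr, "gporder_expr"))
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", expr$cell_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a capture-time table
#'
#' Two columns: `cell_id`, `capture_time`.
#'
#' @param path input/output file.
#' @param sep separator; autodetected on read.
#' @return data frame with `cell_id` and `capture_time`.
#' @export
read_capture_times <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("cell_id", "capture_time") %in% colnames(df)))
    stop(path, ": expected columns cell_id, capture_time")
  df[, c("cell_id", "capture_time")]
}

#' @rdname read_capture_times
#' @param cell_id,capture_time vectors written as the two columns.
#' @export
write_capture_times <- function(cell_id, capture_time, path) {
  utils::write.csv(data.frame(cell_id = cell_id, capture_time = capture_time,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist / restore thinned chain samples
#'
#' One row per stored sample: `iteration`, `log_lik`, `log_sigma_w2`,
#' `log_l`, then the position of every cell (`pos_1..pos_T`, keyed by cell
#' index). The round trip is lossless for the orders and reproduces the
#' traces to full printed precision.
#'
#' @param chain a `gporder_chain`.
#' @param path output/input file (CSV).
#' @return `read_samples` returns a `gporder_chain` carrying the stored
#'   draws and traces (acceptance statistics are not persisted).
#' @export
write_samples <- function(chain, path) {
  stopifnot(inherits(chain, "gporder_chain"))
  P <- orders_to_positions(chain$orders)
  colnames(P) <- paste0("pos_", seq_len(ncol(P)))
  df <- data.frame(iteration = chain$iteration,
                   log_lik = chain$log_lik,
                   log_sigma_w2 = chain$log_sigma_w2,
                   log_l = chain$log_l, P, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  pos_cols <- grep("^pos_", colnames(df))
  if (!length(pos_cols)) stop(path, ": no position columns found")
  P <- as.matrix(df[, pos_cols, drop = FALSE])
  T <- ncol(P)
  orders <- matrix(0L, nrow(P), T)
  for (k in seq_len(nrow(P))) orders[k, P[k, ]] <- seq_len(T)
  thin <- if (nrow(df) > 1) df$iteration[2] - df$iteration[1] else df$iteration[1]
  structure(list(orders = orders, log_lik = df$log_lik,
                 log_sigma_w2 = df$log_sigma_w2, log_l = df$log_l,
                 iteration = df$iteration, T = T,
                 n_iter = df$iteration[nrow(df)], thin = as.integer(thin),
                 burn_in = NA_integer_, seed = NA_integer_, mode = NA_character_,
                 acceptance = NULL, meta = list(source = path)),
            class = "gporder_chain")
}

#' Write a posterior summary as delimited text
#'
#' Writes `<stem>_percell.csv` (cell_id, mean_pseudotime, sd_pseudotime)
#' and `<stem>_position_freq.csv` (dense cell x rank matrix).
#'
#' @param summary a `posterior_summary`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_posterior_summary <- function(summary, stem) {
  stopifnot(inherits(summary, "posterior_summary"))
  p1 <- paste0(stem, "_percell.csv")
  p2 <- paste0(stem, "_position_freq.csv")
  utils::write.csv(summary$percell, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(summary$position_freq),
                              summary$position_freq, check.names = FALSE),
                   p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

# ---- run configuration ----------------------------------------------------

rc_defaults <- function() list(
  mode = "geodesic", chains = 5L, iterations = 10000L, thinning = 10L,
  burn_in = NA_integer_, seed = 1L,
  minicluster = FALSE, minicluster_fraction = 0.125, min_clusters = 5L,
  p1 = 0.2495, p2 = 0.2495, p3 = 0.2495, p4 = 0.2495, p5 = 0.002,
  n0 = NA_integer_, gamma = NA_real_, n3 = NA_integer_, n3a = NA_integer_,
  alpha = 1,
  prior_log_l_mean = log(0.5), prior_log_l_sd = 0.1,
  prior_signal_sd = 0.1, prior_signal_scale = "variance",
  gene_filter = "none", n_keep = 100L,
  anchor = "capture", restrict_start = TRUE, center = TRUE)

#' Run configuration
#'
#' A flat, serializable set of options steering the pipeline: pseudotime
#' mode, move probabilities and tuning constants, prior settings, chain
#' counts and lengths, mini-clustering, gene filtering and the
#' reversal-resolution anchor. Unknown keys are rejected on read so that
#' typos never pass silently.
#'
#' @param ... named options overriding the defaults (see
#'   `gporder:::rc_defaults()` for the full list).
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- rc_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as flat key=value text
#'
#' @param path input/output file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  if (length(bad)) stop(path, ": line ", bad[1], " is not key=value")
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  defs <- rc_defaults()
  unknown <- setdiff(keys, names(defs))
  if (length(unknown))
    stop(path, ": unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- defs
  for (i in seq_along(keys)) {
    d <- defs[[keys[i]]]
    v <- vals[i]
    cfg[[keys[i]]] <- if (v == "NA") d[NA]
                      else if (is.logical(d)) as.logical(v)
                      else if (is.integer(d)) as.integer(v)
                      else if (is.numeric(d)) as.numeric(v)
                      else v
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(vapply(names(cfg), function(k)
    paste0(k, "=", format(cfg[[k]], digits = 17)), character(1)), path)
  invisible(path)
}
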