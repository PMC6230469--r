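#' Proposal-move configuration
#'
#' Tuning constants of the five permutation proposal moves:
#' \enumerate{
#'   \item iterated swapping of neighboring cells (up to `n0` swaps),
#'   \item swapping of cells with short L1 distance,
#'   \item reversing the segment between cells with short L1 distance,
#'   \item up to `n3` random permutations of short segments (segment
#'     parameter drawn from `3..max(n3a, 3)`),
#'   \item reversing the entire ordering.
#' }
#' Moves 2 and 3 pick a cell pair with probability proportional to
#' `exp(-d(c_i, c_j)^2 / gamma)^alpha`, where `d` is the L1 distance of the
#' two cells' expression profiles, so distant cells are rarely exchanged and
#' the smoothness of the trajectory survives the move.
#'
#' @param T number of cells.
#' @param p numeric vector of the five move probabilities (sum 1). Default:
#'   moves 1-4 equiprobable, move 5 with probability 0.002.
#' @param n0 maximum number of neighbor swaps for move 1
#'   (default `max(1, floor(T/4))`).
#' @param gamma distance scale of moves 2/3; `NULL` (default) means the
#'   median squared pairwise L1 distance, making the pair weights scale-free.
#' @param n3 maximum number of short segment permutations for move 4
#'   (default `max(1, floor(T/20))`).
#' @param n3a maximum segment parameter for move 4
#'   (default `max(3, floor(T/12))`).
#' @param alpha tempering exponent in (0, 1] applied to the move-2/3 pair
#'   weights; lowers acceptance contrast when < 1. Default 1.
#' @return object of class `move_config`.
#' @export
move_config <- function(T, p = NULL,
                        n0 = max(1L, floor(T / 4)),
                        gamma = NULL,
                        n3 = max(1L, floor(T / 20)),
                        n3a = max(3L, floor(T / 12)),
                        alpha = 1) {
  if (is.null(p)) p <- c(rep((1 - 0.002) / 4, 4), 0.002)
  if (length(p) != 5 || any(p < 0)) stop("p must be 5 nonnegative probabilities")
  if (abs(sum(p) - 1) > 1e-12) stop("move probabilities must sum to 1")
  if (n0 < 1 || n3 < 1 || n3a < 3) stop("n0, n3 >= 1 and n3a >= 3 required")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  structure(list(T = as.integer(T), p = p, n0 = as.integer(n0), gamma = gamma,
                 n3 = as.integer(n3), n3a = as.integer(n3a), alpha = alpha),
            class = "move_config")
}

#' Pairwise L1 distance table with move-2/3 selection weights
#'
#' Precomputes, for every unordered cell pair, the selection weight
#' `exp(-d^2 / gamma)^alpha` together with its cumulative sum, so that moves
#' 2 and 3 can draw a pair in O(log npairs). Because every unordered cell
#' pair occupies exactly one position pair under any ordering, sampling a
#' cell pair from this table is equivalent to sampling a position pair with
#' the weight of the cells currently at those positions, and the normalizer
#' is the same for every ordering -- which is what makes the two kernels
#' symmetric.
#'
#' @param expr a `gporder_expr` object.
#' @param gamma distance scale; `NULL` for the median squared pairwise L1
#'   distance (positive-distance pairs only).
#' @param alpha tempering exponent in (0, 1].
#' @return object of class `pair_distance_table`.
#' @export
pair_distance_table <- function(expr, gamma = NULL, alpha = 1) {
  stopifnot(inherits(expr, "gporder_expr"))
  T <- n_cells(expr)
  D <- as.matrix(stats::dist(t(expr$values), method = "manhattan"))
  ut <- upper.tri(D)
  idx <- which(ut, arr.ind = TRUE)
  d2 <- D[ut]^2
  if (is.null(gamma)) {
    pos <- d2[d2 > 0]
    gamma <- if (length(pos)) stats::median(pos) else 1
  }
  w <- pmax(exp(-alpha * d2 / gamma), 1e-300)
  structure(list(T = T, a = idx[, 1L], b = idx[, 2L], w = w,
                 cumw = cumsum(w), total = sum(w),
                 gamma = gamma, alpha = alpha, dist = D),
            class = "pair_distance_table")
}

# draw one unordered cell pair (a, b) with probability proportional to its
# weight; returns c(a, b)
draw_pair <- function(pdt) {
  k <- findInterval(stats::runif(1) * pdt$total, pdt$cumw) + 1L
  if (k > length(pdt$a)) k <- length(pdt$a)
  c(pdt$a[k], pdt$b[k])
}

#' Move 1: iterated swapping of neighboring cells
#'
#' Draws the number of swaps uniformly from `1..n0` and that many swap
#' positions uniformly with replacement from `1..T-1`, then applies the
#' adjacent transpositions in order.
#'
#' @param o integer permutation.
#' @param cfg a `move_config`.
#' @return proposed permutation.
#' @export
move1_neighbor_swaps <- function(o, cfg) {
  T <- length(o)
  stopifnot(T >= 2)
  r1 <- sample.int(cfg$n0, 1L)
  P <- sample.int(T - 1L, r1, replace = TRUE)
  for (p in P) o[c(p, p + 1L)] <- o[c(p + 1L, p)]
  o
}

#' Move 2: swap two cells with short L1 distance
#'
#' Samples an unordered pair of positions with probability proportional to
#' the distance weight of the cells occupying them, and exchanges the two
#' cells.
#'
#' @param o integer permutation.
#' @param pdt a `pair_distance_table`.
#' @return proposed permutation.
#' @export
move2_distance_swap <- function(o, pdt) {
  if (length(o) < 2) stop("need at least 2 cells")
  cells <- draw_pair(pdt)
  pos <- integer(length(o)); pos[o] <- seq_along(o)
  ij <- pos[cells]
  o[ij] <- o[rev(ij)]
  o
}

#' Move 3: reverse the segment between two cells with short L1 distance
#'
#' Samples a pair as in move 2 and reverses the ordering of all cells
#' between them, the two selected cells included. Reversing whole segments
#' lets the sampler traverse the permutation space much faster than local
#' swaps when capture-time blocks put many cells in nearly arbitrary
#' starting positions.
#'
#' @inheritParams move2_distance_swap
#' @return proposed permutation.
#' @export
move3_distance_reversal <- function(o, pdt) {
  if (length(o) < 2) stop("need at least 2 cells")
  cells <- draw_pair(pdt)
  pos <- integer(length(o)); pos[o] <- seq_along(o)
  ij <- sort.int(pos[cells])
  o[ij[1]:ij[2]] <- o[ij[2]:ij[1]]
  o
}

#' Move 4: short random permutations
#'
#' Draws a number of segments uniformly from `1..n3`; for each, draws a
#' segment parameter `r3` uniformly from `3..max(n3a, 3)` and a start
#' position uniformly from `1..T-r3`, then applies an independent uniformly
#' random permutation to the cells at positions `k..k+r3`.
#'
#' @param o integer permutation.
#' @param cfg a `move_config`.
#' @return proposed permutation.
#' @export
move4_short_permutations <- function(o, cfg) {
  T <- length(o)
  if (T < 4) stop("move 4 needs at least 4 cells")
  r2 <- sample.int(cfg$n3, 1L)
  lens <- 3:max(cfg$n3a, 3L)
  for (j in seq_len(r2)) {
    r3 <- if (length(lens) == 1L) lens else lens[sample.int(length(lens), 1L)]
    r3 <- min(r3, T - 1L)                 # largest segment still inside 1..T
    k <- sample.int(T - r3, 1L)
    seg <- k:(k + r3)
    o[seg] <- o[seg][sample.int(length(seg))]
  }
  o
}

#' Move 5: reverse the entire ordering
#'
#' The posterior is symmetric under full reversal in geodesic mode, so this
#' move is always accepted and lets chains hop between the two mirrored
#' modes.
#'
#' @param o integer permutation.
#' @return reversed permutation.
#' @export
move5_full_reversal <- function(o) rev(o)

#' Mixture proposal over the five moves
#'
#' Selects one move according to the configured probabilities and applies
#' it. Every component kernel is symmetric (`q(o -> o') = q(o' -> o)`), so
#' the Metropolis-Hastings acceptance ratio needs no proposal correction.
#'
#' @param o integer permutation.
#' @param cfg a `move_config`.
#' @param pdt a `pair_distance_table` (needed for moves 2 and 3).
#' @return list with the proposed `order` and the integer `move` applied.
#' @export
propose_order <- function(o, cfg, pdt) {
  mv <- sample.int(5L, 1L, prob = cfg$p)
  op <- switch(mv,
               move1_neighbor_swaps(o, cfg),
               move2_distance_swap(o, pdt),
               move3_distance_reversal(o, pdt),
               move4_short_permutations(o, cfg),
               move5_full_reversal(o))
  list(order = op, move = mv)
}
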