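# minimal chain object around explicit orders, for summary-level tests
fake_chain <- function(orders, T = ncol(orders)) {
  structure(list(orders = orders, log_lik = rep(0, nrow(orders)),
                 log_sigma_w2 = rep(0, nrow(orders)),
                 log_l = rep(0, nrow(orders)),
                 iteration = seq_len(nrow(orders)), T = T,
                 n_iter = nrow(orders), thin = 1L, burn_in = 0L,
                 seed = NA_integer_, mode = "geodesic",
                 acceptance = NULL, meta = list()),
            class = "gporder_chain")
}

test_that("reversal resolution flips exactly the negatively correlated draws", {
  anchor <- c(1, 1, 2, 2, 3, 3)
  aligned <- 1:6
  flipped <- 6:1
  ch <- fake_chain(rbind(aligned, flipped, aligned))
  out <- resolve_reversals(ch, anchor)
  expect_equal(out$orders[1, ], aligned)
  expect_equal(out$orders[2, ], aligned)       # mirror image flipped back
  expect_equal(out$reversals_resolved, 1)
  # post-condition: no stored order correlates negatively with the anchor
  set.seed(50)
  rnd <- fake_chain(t(replicate(40, sample.int(6))))
  res <- resolve_reversals(rnd, anchor)
  P <- t(apply(res$orders, 1, order))
  cors <- apply(P, 1, function(p) suppressWarnings(cor(p, rank(anchor), method = "spearman")))
  expect_true(all(cors >= 0 | is.na(cors)))
  expect_error(resolve_reversals(ch, rep(2, 6)), "marker")
})

test_that("posterior summaries have the stated shape and degenerate cases", {
  e <- rand_expr(4, 5, seed = 51)
  one <- fake_chain(matrix(c(2, 1, 3, 5, 4), 1))
  s1 <- summarize_posterior(one, e, discard = 0)
  expect_true(all(s1$percell$sd_pseudotime == 0))
  expect_true(all(s1$percell$mean_pseudotime >= 0 & s1$percell$mean_pseudotime <= 1))
  # two draws differing by one adjacent swap: only those cells spread
  o1 <- 1:5; o2 <- c(1, 3, 2, 4, 5)
  s2 <- summarize_posterior(fake_chain(rbind(o1, o2)), e, discard = 0)
  spread <- apply(s2$position_freq, 1, function(r) sum(r > 0))
  expect_equal(as.vector(spread), c(1, 2, 2, 1, 1))
  expect_equal(rowSums(s2$position_freq), setNames(rep(1, 5), e$cell_ids),
               tolerance = 1e-9)
  # modal ordering sorts cells by mean pseudotime
  expect_equal(s2$modal_order, order(s2$percell$mean_pseudotime))
})

test_that("summaries are equivariant under cell relabeling", {
  e <- rand_expr(3, 6, seed = 52)
  orders <- t(replicate(15, sample.int(6)))
  s <- summarize_posterior(fake_chain(orders), e, discard = 0)
  rel <- c(3, 1, 2, 6, 5, 4)                    # new index of each old cell
  e2 <- expression_matrix(e$values[, order(rel)])
  orders2 <- matrix(rel[orders], nrow(orders))
  s2 <- summarize_posterior(fake_chain(orders2), e2, discard = 0)
  expect_equal(s2$percell$mean_pseudotime[rel], s$percell$mean_pseudotime)
  expect_equal(s2$percell$sd_pseudotime[rel], s$percell$sd_pseudotime)
})

test_that("rank-mode summaries use the equidistant grid", {
  e <- rand_expr(2, 4, seed = 53)
  s <- summarize_posterior(fake_chain(matrix(1:4, 1)), e, mode = "rank",
                           discard = 0)
  expect_equal(s$percell$mean_pseudotime, rank_pseudotimes(4))
})

test_that("classical MDS reproduces exactly embeddable configurations", {
  # three mutually equidistant orders: cyclic rotations
  rot <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  m <- mds_positions(fake_chain(rot), discard = 0)
  D <- as.matrix(dist(m$points))
  off <- D[upper.tri(D)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-8)
  # any 3 position vectors embed exactly in 2D: distances are preserved
  set.seed(54)
  three <- t(replicate(3, sample.int(7)))
  m3 <- mds_positions(fake_chain(three), discard = 0)
  P <- t(apply(three, 1, order))
  expect_equal(as.vector(dist(m3$points)), as.vector(dist(P)), tolerance = 1e-8)
  # duplicated draws land on the same point
  dup <- fake_chain(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 1, 3, 4)))
  md <- mds_positions(dup, discard = 0)
  expect_equal(md$points[1, ], md$points[2, ], tolerance = 1e-8)
})

test_that("gene-set scores average the requested genes over mean pseudotime", {
  e <- rand_expr(5, 6, seed = 55)
  s <- summarize_posterior(fake_chain(matrix(1:6, 1)), e, discard = 0)
  one <- gene_set_score(e, e$gene_ids[2], s)
  expect_equal(one$score, as.numeric(e$values[2, ]))
  all_g <- gene_set_score(e, e$gene_ids, s)
  expect_equal(all_g$score, as.numeric(colMeans(e$values)))
  shuffled <- gene_set_score(e, rev(e$gene_ids), s)
  expect_equal(shuffled$score, all_g$score)
  expect_error(gene_set_score(e, c("g2", "nope"), s), "nope")
})

test_that("position uncertainty is higher where cells crowd in input time", {
  # cells dense in the middle of the process, sparse at the ends: the
  # posterior should be least certain about the crowded cells
  set.seed(56)
  hits <- 0
  for (rep_i in 1:5) {
    T <- 20
    ts <- sort(c(runif(6, 0, 0.3), runif(8, 0.45, 0.55), runif(6, 0.7, 1)))
    d2 <- outer(ts, ts, "-")^2
    ng <- 12
    Y <- matrix(0, ng, T)
    for (g in seq_len(ng)) {
      K <- exp(-d2 / (2 * 0.4^2))
      Y[g, ] <- crossprod(chol(K + diag(1e-8, T)), rnorm(T)) + 0.5 * rnorm(T)
    }
    sh <- sample.int(T)
    e <- center_data(expression_matrix(Y[, sh]))
    ch <- run_chain(e, n_iter = 8000, seed = 500 + rep_i, thin = 10,
                    fixed_params = gp_params(1, 0.4, 0.25),
                    restrict_start = FALSE)
    ch <- resolve_reversals(ch, rank(ts)[sh])
    s <- summarize_posterior(ch, e)
    # local crowding: distance to the 3rd nearest input time, inverted
    crowd <- -apply(abs(outer(ts[sh], ts[sh], "-")), 1, function(r) sort(r)[4])
    if (cor(crowd, s$percell$sd_pseudotime, method = "spearman") > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})
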