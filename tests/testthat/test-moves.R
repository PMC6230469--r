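test_that("move config defaults and validation follow the stated rules", {
  cfg <- move_config(90)
  expect_equal(cfg$n0, 22L)                 # floor(T/4)
  expect_equal(cfg$n3, 4L)                  # floor(T/20)
  expect_equal(cfg$n3a, 7L)                 # floor(T/12)
  expect_equal(cfg$p[5], 0.002)
  expect_equal(sum(cfg$p), 1)
  expect_equal(cfg$p[1], cfg$p[2])
  # floors for tiny T
  tiny <- move_config(5)
  expect_equal(c(tiny$n0, tiny$n3, tiny$n3a), c(1L, 1L, 3L))
  expect_error(move_config(10, p = c(0.3, 0.3, 0.3, 0.3, 0.3)), "sum")
  expect_error(move_config(10, alpha = 0), "alpha")
})

test_that("pair weights are positive, symmetric-by-construction and scale-free", {
  e <- rand_expr(4, 6, seed = 3)
  pdt <- pair_distance_table(e)
  expect_equal(length(pdt$w), 15)           # T(T-1)/2 unordered pairs
  expect_true(all(pdt$w > 0))
  expect_equal(pdt$gamma, median(pdt$dist[upper.tri(pdt$dist)]^2))
  # gamma -> Inf limit: uniform weights
  pdt_inf <- pair_distance_table(e, gamma = 1e12)
  expect_equal(max(pdt_inf$w) / min(pdt_inf$w), 1, tolerance = 1e-6)
})

test_that("move 1 applies between 1 and n0 adjacent transpositions", {
  set.seed(5)
  o <- 1:6
  cfg1 <- move_config(6, n0 = 1)
  for (i in 1:50) {
    op <- move1_neighbor_swaps(o, cfg1)
    d <- which(op != o)
    expect_equal(length(d), 2L)             # exactly one adjacent swap
    expect_equal(diff(d), 1L)
    expect_equal(op[d], o[rev(d)])
  }
  # repeated swap positions can cancel: with T = 2 the identity must occur
  cfg2 <- move_config(2, n0 = 2)
  outs <- replicate(200, paste(move1_neighbor_swaps(1:2, cfg2), collapse = ""))
  expect_setequal(unique(outs), c("12", "21"))
})

test_that("moves 2 and 3 act on the sampled short-distance pair", {
  # cells 2 and 4 identical, every other pair far apart: the (2,4) pair
  # carries essentially all selection weight
  Y <- matrix(c(0, 100, 200, 100, 300), 1, 5) + rbind(seq(0, 4e-6, 1e-6))
  e <- expression_matrix(Y)
  pdt <- pair_distance_table(e, gamma = 1)
  set.seed(6)
  expect_equal(move2_distance_swap(1:5, pdt), c(1, 4, 3, 2, 5))
  expect_equal(move3_distance_reversal(1:5, pdt), c(1, 4, 3, 2, 5))
  # same cells under a shuffled order: positions follow the cells
  o <- c(2, 1, 4, 5, 3)
  expect_equal(move2_distance_swap(o, pdt), c(4, 1, 2, 5, 3))
  rev_seg <- o; rev_seg[1:3] <- o[3:1]
  expect_equal(move3_distance_reversal(o, pdt), rev_seg)
})

test_that("with equal distances moves 2 selects pairs uniformly", {
  # equidistant cells: regular simplex in expression space
  e <- expression_matrix(diag(4) * 5 + 1)
  pdt <- pair_distance_table(e)
  set.seed(7)
  n <- 20000
  pair_id <- replicate(n, {
    op <- move2_distance_swap(1:4, pdt)
    paste(which(op != 1:4), collapse = "")
  })
  counts <- table(pair_id)
  expect_equal(length(counts), 6)           # all C(4,2) pairs occur
  expect_gt(chisq.test(counts)$p.value, 1e-3)
})

test_that("move 3 reverses the whole sequence when the end pair is drawn", {
  Y <- matrix(c(0, 50, 100, 150, 0.001), 1, 5)   # cells 1 and 5 nearly identical
  e <- expression_matrix(Y)
  pdt <- pair_distance_table(e, gamma = 1)
  set.seed(8)
  expect_equal(move3_distance_reversal(1:5, pdt), 5:1)
})

test_that("move 4 permutes a bounded segment and leaves the rest fixed", {
  set.seed(9)
  cfg <- move_config(8, n3 = 1, n3a = 3)
  saw_change <- FALSE
  for (i in 1:100) {
    o <- sample.int(8)
    op <- move4_short_permutations(o, cfg)
    ch <- which(op != o)
    if (length(ch)) {
      saw_change <- TRUE
      expect_lte(max(ch) - min(ch), 3)      # inside one segment of r3+1 = 4 cells
      expect_setequal(op[min(ch):max(ch)], o[min(ch):max(ch)])
    }
  }
  expect_true(saw_change)
  expect_error(move4_short_permutations(1:3, move_config(5)), "at least 4")
})

test_that("move 5 is the involutive full reversal", {
  expect_equal(move5_full_reversal(1:3), 3:1)
  o <- sample.int(9)
  expect_equal(move5_full_reversal(move5_full_reversal(o)), o)
})

test_that("every move returns a valid permutation", {
  set.seed(10)
  for (i in 1:40) {
    T <- sample(4:12, 1)
    e <- rand_expr(3, T, seed = 300 + i)
    pdt <- pair_distance_table(e)
    cfg <- move_config(T)
    o <- sample.int(T)
    for (op in list(move1_neighbor_swaps(o, cfg),
                    move2_distance_swap(o, pdt),
                    move3_distance_reversal(o, pdt),
                    move4_short_permutations(o, cfg),
                    move5_full_reversal(o),
                    propose_order(o, cfg, pdt)$order))
      expect_setequal(op, seq_len(T))
  }
})

test_that("the mixture fires moves at their configured probabilities", {
  e <- rand_expr(3, 6, seed = 12)
  pdt <- pair_distance_table(e)
  cfg <- move_config(6, p = c(0.4, 0.25, 0.2, 0.1, 0.05))
  set.seed(13)
  n <- 20000
  mv <- replicate(n, propose_order(1:6, cfg, pdt)$move)
  expect_gt(chisq.test(table(factor(mv, levels = 1:5)), p = cfg$p)$p.value, 1e-3)
  # a degenerate mixture is deterministic
  cfg5 <- move_config(6, p = c(0, 0, 0, 0, 1))
  expect_equal(propose_order(1:6, cfg5, pdt)$order, 6:1)
})

test_that("moves 1-4 reach the whole permutation space at T = 4", {
  e <- rand_expr(3, 4, seed = 14)
  pdt <- pair_distance_table(e)
  cfg <- move_config(4, p = c(0.25, 0.25, 0.25, 0.25, 0))
  set.seed(15)
  o <- 1:4
  seen <- new.env()
  for (i in 1:4000) {
    o <- propose_order(o, cfg, pdt)$order
    assign(paste(o, collapse = ""), TRUE, envir = seen)
  }
  expect_equal(length(ls(seen)), 24)
})
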