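test_that("grand-mean centering zeroes the mean and preserves variance", {
  e <- rand_expr(6, 9, seed = 81)
  e$values <- e$values + 3.7
  e <- expression_matrix(e$values)
  cen <- center_data(e)
  expect_lt(abs(mean(cen$values)), 1e-10)
  expect_equal(cen$V, e$V, tolerance = 1e-12)
  const <- expression_matrix(matrix(2.5, 3, 4))
  expect_equal(unname(center_data(const)$values), matrix(0, 3, 4))
})

test_that("ANOVA filter matches aov and ranks flat genes last", {
  set.seed(82)
  ct <- rep(1:3, each = 4)
  Y <- matrix(rnorm(5 * 12), 5, 12)
  Y[1, ] <- Y[1, ] + c(0, 3, 6)[ct]          # strongly separated means
  Y[5, ] <- rnorm(12, 0, 1)                  # no group structure
  e <- expression_matrix(Y, capture_times = ct)
  filt <- anova_gene_filter(e, n_keep = 5)
  tab <- attr(filt, "anova")
  # dual route: compare per-gene F and p with stats::aov
  for (g in 1:5) {
    fit <- summary(aov(Y[g, ] ~ factor(ct)))[[1]]
    expect_equal(tab$F[g], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(tab$p[g], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(which.min(tab$p), 1L)
  # top-1 keeps the separated gene; n_keep = n_g is the identity
  expect_equal(anova_gene_filter(e, n_keep = 1)$gene_ids, e$gene_ids[1])
  expect_equal(anova_gene_filter(e, n_keep = 5)$gene_ids, e$gene_ids)
  e_nc <- expression_matrix(Y)
  expect_error(anova_gene_filter(e_nc), "capture times")
})

test_that("mean/variance filter favors genes high in both", {
  set.seed(83)
  Y <- rbind(high = rnorm(20, 10, 3),
             lowmean = rnorm(20, -10, 3),
             lowvar = rnorm(20, 10, 0.01),
             zero = rep(0, 20))
  e <- expression_matrix(Y)
  top1 <- mean_variance_filter(e, 1)
  expect_equal(top1$gene_ids, "high")
  expect_equal(mean_variance_filter(e, 4)$gene_ids, e$gene_ids)
  # invariant to cell order
  e_shuf <- expression_matrix(Y[, sample.int(20)])
  expect_equal(mean_variance_filter(e_shuf, 2)$gene_ids,
               mean_variance_filter(e, 2)$gene_ids)
})

test_that("expression and capture-time files round-trip losslessly", {
  e <- rand_expr(4, 6, seed = 84)
  f <- tempfile(fileext = ".csv")
  write_expression(e, f)
  back <- read_expression(f)
  expect_equal(back$values, e$values, tolerance = 1e-12)
  expect_equal(back$gene_ids, e$gene_ids)
  expect_equal(back$cell_ids, e$cell_ids)
  # tab-separated autodetection
  ft <- tempfile(fileext = ".tsv")
  write_expression(e, ft, sep = "\t")
  expect_equal(read_expression(ft)$values, e$values, tolerance = 1e-12)
  fc <- tempfile(fileext = ".csv")
  write_capture_times(e$cell_ids, rep(1:2, each = 3), fc)
  ct <- read_capture_times(fc)
  expect_equal(ct$cell_id, e$cell_ids)
  e2 <- attach_capture_times(e, ct$cell_id, ct$capture_time)
  expect_equal(e2$capture_times, rep(1:2, each = 3))
  expect_error(read_expression(tempfile()), "no such file")
})

test_that("chain samples round-trip through the columnar format", {
  e <- center_data(rand_expr(3, 6, seed = 85))
  ch <- run_chain(e, n_iter = 200, seed = 86, thin = 10)
  f <- tempfile(fileext = ".csv")
  write_samples(ch, f)
  back <- read_samples(f)
  expect_identical(back$orders, ch$orders)
  expect_equal(back$log_lik, ch$log_lik, tolerance = 1e-12)
  expect_equal(back$log_sigma_w2, ch$log_sigma_w2, tolerance = 1e-12)
  expect_equal(back$iteration, ch$iteration)
  expect_equal(back$thin, ch$thin)
})

test_that("run configurations serialize to key=value text and reject typos", {
  cfg <- run_config(iterations = 5000L, mode = "rank", alpha = 0.7)
  f <- tempfile(fileext = ".txt")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back$iterations, 5000L)
  expect_equal(back$mode, "rank")
  expect_equal(back$alpha, 0.7)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(cfg))], tolerance = 1e-12)
  expect_error(run_config(iterattions = 10), "unknown")
  writeLines(c("mode=rank", "bogus_key=3"), f)
  expect_error(read_run_config(f), "bogus_key")
})

test_that("the CLI drives the full simulate/run/converge/summarize workflow", {
  td <- file.path(tempdir(), "cli_ws")
  dir.create(td, showWarnings = FALSE)
  simdir <- file.path(td, "sim")
  cli_main(c("simulate", "--preset", "sim1", "--seed", "3", "--out-dir", simdir))
  expect_true(file.exists(file.path(simdir, "expression.csv")))
  expect_true(file.exists(file.path(simdir, "capture_times.csv")))
  rundir <- file.path(td, "run")
  args_run <- c("run", "--expression", file.path(simdir, "expression.csv"),
                "--capture-times", file.path(simdir, "capture_times.csv"),
                "--chains", "2", "--iterations", "300", "--thin", "10",
                "--seed", "4", "--out-dir", rundir)
  suppressMessages(cli_main(args_run))
  ch1 <- file.path(rundir, "chain_1.csv")
  ch2 <- file.path(rundir, "chain_2.csv")
  expect_true(file.exists(ch1) && file.exists(ch2))
  expect_true(file.exists(file.path(rundir, "resolved_config.txt")))
  # identical config + seeds reproduce identical sample files
  rundir2 <- file.path(td, "run2")
  args_run[which(args_run == rundir)] <- rundir2
  suppressMessages(cli_main(args_run))
  expect_identical(readLines(ch1), readLines(file.path(rundir2, "chain_1.csv")))
  rep_csv <- file.path(td, "convergence.csv")
  suppressMessages(cli_main(c("converge", "--samples", paste(ch1, ch2, sep = ","),
                              "--out", rep_csv)))
  expect_true(file.exists(rep_csv))
  expect_true(all(c("rhat_loglik", "rhat_l1") %in% colnames(read.csv(rep_csv))))
  stem <- file.path(td, "summary")
  suppressMessages(cli_main(c("summarize", "--samples", paste(ch1, ch2, sep = ","),
                              "--expression", file.path(simdir, "expression.csv"),
                              "--capture-times", file.path(simdir, "capture_times.csv"),
                              "--out-stem", stem)))
  percell <- read.csv(paste0(stem, "_percell.csv"))
  expect_equal(nrow(percell), 90)
  expect_true(all(percell$mean_pseudotime >= 0 & percell$mean_pseudotime <= 1))
  mapf <- file.path(td, "map.csv")
  suppressMessages(cli_main(c("minicluster", "--expression",
                              file.path(simdir, "expression.csv"),
                              "--capture-times", file.path(simdir, "capture_times.csv"),
                              "--out", mapf)))
  expect_equal(nrow(read.csv(mapf)), 90)
  expect_error(cli_main(c("frobnicate")), "unknown subcommand")
  expect_error(cli_main(c("run", "--expression")), "out-dir")
})

test_that("a single stored draw summarizes with zero spread end-to-end", {
  td <- file.path(tempdir(), "cli_one")
  dir.create(td, showWarnings = FALSE)
  e <- center_data(rand_expr(3, 8, seed = 87))
  ch <- run_chain(e, n_iter = 10, seed = 88, thin = 10)
  f <- file.path(td, "one.csv")
  write_samples(ch, f)
  ef <- file.path(td, "expr.csv")
  write_expression(e, ef)
  stem <- file.path(td, "s")
  suppressMessages(cli_main(c("summarize", "--samples", f,
                              "--expression", ef, "--out-stem", stem)))
  percell <- read.csv(paste0(stem, "_percell.csv"))
  expect_true(all(percell$sd_pseudotime == 0))
})
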