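test_that("noise-free conflict-free input is returned unchanged with no losses", {
  M <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(0, 0, 0))
  fit <- run_infer(scs_matrix(M), alpha = 0.01, beta = 0.01, k = 0,
                   refine = FALSE)
  expect_equal(fit$F_star, M, ignore_attr = TRUE)
  expect_equal(fit$n_losses, 0L)
  expect_equal(fit$status, "optimal")
})

test_that("refinement never scores below the solver objective", {
  set.seed(127)
  b <- simulate_scs(sim_config(n_subclones = 4, n_cells = 20, n_mutations = 6,
                               n_deletions = 1, alpha = 0.1, beta = 1e-3,
                               gamma = 0.1))
  fit <- run_infer(b$observed, alpha = 0.1, beta = 1e-3, k = 1,
                   neighbor_samples = 10, max_iterations = 10, seed = 1)
  expect_gte(fit$hc_objective, fit$ilp_objective - 1e-9)
  expect_equal(fit$n_losses, sum(fit$tree$type == "loss"))
  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_cells, 20L)
  td <- tidy(fit)
  expect_equal(sum(td$n_cells), 20L)
  expect_true(all(c("label", "type", "parent") %in% names(td)))
})

test_that("a loss cap of zero forces a loss-free explanation", {
  M <- rbind(c(1, 0), c(1, 1), c(0, 1))
  fit <- run_infer(scs_matrix(M), alpha = 0.05, beta = 0.05, k = 1,
                   max_losses = 0, refine = FALSE)
  expect_equal(fit$n_losses, 0L)
  expect_equal(fit$status, "optimal")
})

test_that("same configuration and seed reproduce the fit", {
  set.seed(131)
  b <- simulate_scs(sim_config(n_subclones = 3, n_cells = 12, n_mutations = 5,
                               n_deletions = 1, alpha = 0.05, beta = 1e-3,
                               gamma = 0.05))
  f1 <- run_infer(b$observed, alpha = 0.05, beta = 1e-3, seed = 9,
                  neighbor_samples = 5, max_iterations = 5)
  f2 <- run_infer(b$observed, alpha = 0.05, beta = 1e-3, seed = 9,
                  neighbor_samples = 5, max_iterations = 5)
  expect_equal(f1$log_likelihood, f2$log_likelihood)
  expect_identical(tibble::as_tibble(f1$tree), tibble::as_tibble(f2$tree))
  expect_identical(f1$attachment, f2$attachment)
  rep <- run_report(f1)
  expect_named(rep, c("status", "ilp_objective", "hc_objective", "n_losses",
                      "wall_time", "config"))
})

test_that("plot methods return ggplot objects", {
  set.seed(137)
  b <- simulate_scs(sim_config(n_subclones = 3, n_cells = 10, n_mutations = 4,
                               n_deletions = 1, alpha = 0.05, beta = 1e-3,
                               gamma = 0.05))
  fit <- run_infer(b$observed, alpha = 0.05, beta = 1e-3,
                   neighbor_samples = 5, max_iterations = 3, seed = 2)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_tree(fit$tree), "ggplot")
  expect_s3_class(plot_hc_trace(fit), "ggplot")
})

test_that("the command-line tool wires simulate, infer and evaluate together", {
  script <- system.file("exec", "dollotree", package = "dollotree")
  skip_if(script == "", "exec script not installed")
  outdir <- withr::local_tempdir()
  st <- system2("Rscript", c(script, "simulate", "--subclones", "3",
                             "--cells", "15", "--mutations", "4",
                             "--deletions", "1", "-a", "0.05", "-b", "0.001",
                             "-g", "0.05", "--seed", "5", "--outdir", outdir),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(outdir, "observed.txt")))
  out_gv <- file.path(outdir, "inferred.gv")
  report <- file.path(outdir, "report.json")
  st <- system2("Rscript", c(script, "infer", "-i",
                             file.path(outdir, "observed.txt"),
                             "-a", "0.05", "-b", "0.001", "-k", "1",
                             "--ns", "5", "--mi", "3", "--seed", "1",
                             "-o", out_gv, "--report", report),
                stdout = FALSE, stderr = FALSE)
  expect_equal(st, 0L)
  expect_true(file.exists(out_gv))
  rep <- jsonlite::read_json(report)
  expect_true(rep$hc_objective >= rep$ilp_objective - 1e-9)
  ev <- system2("Rscript", c(script, "evaluate", "--truth",
                             file.path(outdir, "truth_tree.gv"),
                             "--inferred", out_gv), stdout = TRUE)
  expect_match(ev[1], "ad_f\tdl_f")
  vals <- as.numeric(strsplit(ev[2], "\t")[[1]])
  expect_true(all(vals >= 0 & vals <= 1))
})
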