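test_that("clonal trees respect the construction rules", {
  set.seed(89)
  # single clone, no deletions: one chain carrying all gains
  t1 <- generate_clonal_tree(sim_config(n_subclones = 1, n_cells = 0,
                                        n_mutations = 3, n_deletions = 0))
  expect_equal(sum(t1$type == "gain"), 3L)
  expect_equal(sum(t1$type == "loss"), 0L)
  expect_equal(length(node_state(t1, max(t1$id))), 3L)

  for (i in 1:10) {
    tr <- generate_clonal_tree(sim_config(n_subclones = 9, n_cells = 0,
                                          n_mutations = 30, n_deletions = 5))
    expect_true(is_dollo_1(tr))
    # every mutation gained exactly once; deleted mutations pairwise distinct
    expect_equal(sort(tr$mutation[tr$type == "gain"]), 1:30)
    del <- tr$mutation[tr$type == "loss"]
    expect_lte(length(del), 5L)
    expect_equal(anyDuplicated(del), 0L)
    # each loss deletes a mutation present in its parent's state
    S <- dollotree:::node_state_matrix(tr)
    for (r in which(tr$type == "loss")) {
      p <- match(tr$parent[r], tr$id)
      expect_equal(unname(S[p, tr$mutation[r]]), 1L)
    }
  }
  # impossible deletion placement fails loudly: mutations < deletions
  expect_error(sim_config(n_subclones = 2, n_mutations = 1, n_deletions = 2))
})

test_that("cells are attached uniformly over clone-level nodes", {
  set.seed(97)
  tr <- generate_clonal_tree(sim_config(n_subclones = 5, n_cells = 0,
                                        n_mutations = 10, n_deletions = 2))
  pool <- attr(tr, "clone_nodes")
  cells <- sample_cells(tr, 20000)
  counts <- table(factor(cells$attachment$node, levels = sort(unique(pool))))
  # expected multiplicity per node id (duplicate representatives get weight)
  expected <- table(factor(pool, levels = sort(unique(pool)))) / length(pool)
  chi <- suppressWarnings(stats::chisq.test(counts, p = as.numeric(expected)))
  expect_gt(chi$p.value, 1e-4)
  # genotypes are the node states
  S <- dollotree:::node_state_matrix(tr)
  idx <- match(cells$attachment$node, tr$id)
  expect_equal(cells$genotypes, S[idx, , drop = FALSE], ignore_attr = TRUE)
  # degenerate: no cells
  none <- sample_cells(tr, 0)
  expect_equal(nrow(none$genotypes), 0L)
})

test_that("noise flips and masking hit their nominal rates", {
  set.seed(101)
  truth <- matrix(1L, 400, 300)
  obs <- add_noise(truth, alpha = 0.1, beta = 0, gamma = 0)
  frac0 <- mean(obs == 0L, na.rm = TRUE)
  sigma <- sqrt(0.1 * 0.9 / length(truth))
  expect_lt(abs(frac0 - 0.1), 3 * sigma)

  mixed <- matrix(rbinom(120000, 1, 0.5), 400, 300)
  noisy <- add_noise(mixed, alpha = 0, beta = 0, gamma = 0.1)
  fracNA <- mean(is.na(noisy))
  sigmaNA <- sqrt(0.1 * 0.9 / length(mixed))
  expect_lt(abs(fracNA - 0.1), 3 * sigmaNA)

  expect_equal(unclass(add_noise(mixed, 0, 0, 0)), mixed, ignore_attr = TRUE)
  expect_true(all(is.na(add_noise(mixed, 0, 0, 1))))
})

test_that("bundles are reproducible and internally consistent", {
  cfg <- sim_config(n_subclones = 5, n_cells = 25, n_mutations = 8,
                    n_deletions = 2, alpha = 0.1, beta = 1e-4, gamma = 0.1,
                    seed = 103)
  b1 <- simulate_scs(cfg)
  b2 <- simulate_scs(cfg)
  expect_identical(b1$observed, b2$observed)
  expect_identical(tibble::as_tibble(b1$truth_tree),
                   tibble::as_tibble(b2$truth_tree))
  expect_equal(b1$truth_matrix,
               genotype_matrix(b1$truth_tree, b1$truth_attachment))
  expect_true(is_dollo_1(b1$truth_tree))
  expect_equal(dim(b1$observed), c(25L, 8L))
})

test_that("without deletions and noise the observed matrix is conflict-free", {
  set.seed(107)
  for (i in 1:5) {
    b <- simulate_scs(sim_config(n_subclones = 5, n_cells = 20,
                                 n_mutations = 8, n_deletions = 0,
                                 alpha = 0, beta = 0, gamma = 0))
    expect_true(is_conflict_free(unclass(b$observed)))
  }
})
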