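test_that("SPR reattaches the pruned subtree under the new parent", {
  # root -> a+ -> b+ ; root -> c+ : move c+ under b+
  tr <- phylo_tree(tibble::tibble(
    id = 1:4, parent = c(NA, 1L, 2L, 1L),
    type = c("root", "gain", "gain", "gain"),
    mutation = c(NA, 1L, 2L, 3L), copy = rep(NA_integer_, 4)), 3)
  moved <- spr_move(tr, 4L, 3L)
  expect_equal(moved$parent[moved$id == 4L], 3L)
  expect_equal(sort(moved$id), sort(tr$id))  # same node multiset
  expect_true(is_dollo_k(moved, 1))
})

test_that("SPR preconditions are enforced", {
  tr <- phylo_tree(tibble::tibble(
    id = 1:3, parent = c(NA, 1L, 2L), type = c("root", "gain", "gain"),
    mutation = c(NA, 1L, 2L), copy = rep(NA_integer_, 3)), 2)
  expect_error(spr_move(tr, 1L, 2L), "root")
  expect_error(spr_move(tr, 2L, 3L), "subtree")
  expect_error(spr_move(tr, 3L, 2L), "already the parent")
  expect_error(spr_move(tr, 9L, 1L), "unknown node")
})

test_that("losses invalidated by a move are contracted", {
  # root -> a+ -> b+ -> b-(4) ; moving the subtree at b- under the root
  # strands the loss (b never gained above), so it is contracted and its
  # child survives
  tr <- phylo_tree(tibble::tibble(
    id = 1:5, parent = c(NA, 1L, 2L, 3L, 4L),
    type = c("root", "gain", "gain", "loss", "gain"),
    mutation = c(NA, 1L, 2L, 2L, 3L), copy = c(NA, NA, NA, 1L, NA)), 3)
  moved <- spr_move(tr, 4L, 1L)
  expect_false(4L %in% moved$id)          # loss contracted
  expect_equal(moved$parent[moved$id == 5L], 1L)  # child re-attached
  expect_true(is_dollo_k(moved, 1))
})

test_that("neighbor sampling is exhaustive over valid pairs and reproducible", {
  # 2-node tree: no valid move
  t2 <- phylo_tree(tibble::tibble(
    id = 1:2, parent = c(NA, 1L), type = c("root", "gain"),
    mutation = c(NA, 1L), copy = c(NA, NA)), 1)
  expect_identical(sample_neighbor(t2), t2)

  tr <- phylo_tree(tibble::tibble(
    id = 1:5, parent = c(NA, 1L, 2L, 1L, 4L),
    type = c("root", "gain", "gain", "gain", "gain"),
    mutation = c(NA, 1L, 2L, 3L, 4L), copy = rep(NA_integer_, 5)), 4)
  pairs <- dollotree:::valid_spr_pairs(tr)
  seen <- character(0)
  set.seed(71)
  for (i in 1:500) {
    nb <- sample_neighbor(tr)
    key <- paste(nb$parent[order(nb$id)], collapse = ",")
    seen <- union(seen, key)
  }
  # each valid (u, v) yields a distinct parent vector here
  expect_equal(length(seen), nrow(pairs))
  set.seed(123); a <- sample_neighbor(tr)
  set.seed(123); b <- sample_neighbor(tr)
  expect_identical(a, b)
})

test_that("random SPR moves with contraction preserve the Dollo property", {
  set.seed(73)
  for (rep in 1:20) {
    tr <- random_dollo1_tree(n_mutations = 6, n_subclones = 4, n_deletions = 2)
    for (i in 1:10) {
      tr2 <- sample_neighbor(tr)
      expect_true(is_dollo_1(tr2))
      tr <- tr2
    }
  }
})

test_that("hill climbing improves monotonically and is reproducible", {
  set.seed(79)
  bundle <- simulate_scs(sim_config(n_subclones = 4, n_cells = 20,
                                    n_mutations = 6, n_deletions = 1,
                                    alpha = 0.1, beta = 1e-3, gamma = 0.1))
  I <- bundle$observed
  r <- error_rates(0.1, 1e-3)
  start <- bundle$truth_tree
  base <- best_attachment(start, I, r)$log_likelihood

  # zero iterations: unchanged start and its own score
  hc0 <- hill_climb(start, I, r, hillclimb_config(5, 0, seed = 1))
  expect_identical(tibble::as_tibble(hc0$tree), tibble::as_tibble(start))
  expect_equal(hc0$log_likelihood, base)

  hc <- hill_climb(start, I, r, hillclimb_config(10, 15, seed = 2))
  expect_gte(hc$log_likelihood, base)
  expect_true(all(diff(hc$trace$current) >= 0))
  expect_equal(max(hc$trace$best), hc$log_likelihood)
  expect_true(is_dollo_1(hc$tree))

  hc_again <- hill_climb(start, I, r, hillclimb_config(10, 15, seed = 2))
  expect_equal(hc_again$log_likelihood, hc$log_likelihood)
  expect_identical(tibble::as_tibble(hc_again$tree), tibble::as_tibble(hc$tree))
})

test_that("on noise-free data the truth tree is a fixed point up to ties", {
  set.seed(83)
  bundle <- simulate_scs(sim_config(n_subclones = 4, n_cells = 15,
                                    n_mutations = 5, n_deletions = 1,
                                    alpha = 0, beta = 0, gamma = 0))
  I <- bundle$observed
  r <- error_rates(0, 0)
  truth_ll <- best_attachment(bundle$truth_tree, I, r)$log_likelihood
  hc <- hill_climb(bundle$truth_tree, I, r, hillclimb_config(10, 10, seed = 3))
  expect_equal(hc$log_likelihood, truth_ll)
})
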