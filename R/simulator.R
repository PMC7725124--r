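#' Simulation configuration
#'
#' Parameters of the clonal-tree simulator. The defaults are the study
#' conditions used throughout the package's evaluation: 9 subclones, 100
#' cells, 30 mutations, at most 5 deleted mutations, false-negative rate
#' 0.1, false-positive rate 1e-4 and missing-entry rate 0.1.
#'
#' @param n_subclones number of subclone nodes in the random clonal tree.
#' @param n_cells number of sampled cells.
#' @param n_mutations number of mutations.
#' @param n_deletions number of deletion (loss) nodes added to the tree;
#'   each deletes a distinct mutation, so the ground truth is Dollo(1).
#' @param alpha probability of flipping a true 1 to 0 (false negative).
#' @param beta probability of flipping a true 0 to 1 (false positive).
#' @param gamma probability that an entry is masked as missing.
#' @param seed optional integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subclones = 9L, n_cells = 100L, n_mutations = 30L,
                       n_deletions = 5L, alpha = 0.1, beta = 1e-4,
                       gamma = 0.1, seed = NULL) {
  stopifnot(n_subclones >= 1, n_cells >= 0, n_mutations >= 1,
            n_deletions >= 0, n_deletions <= n_mutations,
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            gamma >= 0, gamma <= 1)
  structure(list(n_subclones = as.integer(n_subclones),
                 n_cells = as.integer(n_cells),
                 n_mutations = as.integer(n_mutations),
                 n_deletions = as.integer(n_deletions),
                 alpha = alpha, beta = beta, gamma = gamma, seed = seed),
            class = "sim_config")
}

#' Generate a random clonal tree with deletions
#'
#' Builds a random tree of `n_subclones` nodes by repeatedly attaching a new
#' subclone as a child of a random existing one (the first subclone is the
#' founding clone, child of the germline root). Each mutation is assigned to
#' a uniformly random subclone; a subclone carrying several gains is
#' expanded into a chain of gain nodes (in mutation-index order), and a
#' subclone carrying none shares its parent's node. Then `n_deletions` loss
#' nodes are attached, each as a new child of a uniformly chosen clone-level
#' node with at least one eligible mutation — one that is present in the
#' parent's state and has not already been deleted — deleting one eligible
#' mutation uniformly at random. Deleted mutations are pairwise distinct, so
#' the result is a Dollo(1) tree.
#'
#' Uses the current RNG state; seed upstream (see [simulate_scs()]).
#'
#' @param config a [sim_config()].
#' @return a [phylo_tree()] with attribute `"clone_nodes"`: the node ids of
#'   the germline, each subclone and each deletion node (the sampling
#'   population for [sample_cells()]).
#' @export
generate_clonal_tree <- function(config) {
  S <- config$n_subclones
  M <- config$n_mutations
  parent_clone <- c(0L, if (S > 1)
    vapply(2:S, function(i) sample.int(i - 1L, 1L), integer(1)))
  clone_of_mut <- sample.int(S, M, replace = TRUE)
  nodes <- tibble::tibble(id = 1L, parent = NA_integer_, type = "root",
                          mutation = NA_integer_, copy = NA_integer_)
  next_id <- 2L
  rep_node <- integer(S)  # representative (deepest) tree node of each subclone
  for (s in seq_len(S)) {
    anchor <- if (parent_clone[s] == 0L) 1L else rep_node[parent_clone[s]]
    for (mu in which(clone_of_mut == s)) {
      nodes <- tibble::add_row(nodes, id = next_id, parent = anchor,
                               type = "gain", mutation = mu, copy = NA_integer_)
      anchor <- next_id
      next_id <- next_id + 1L
    }
    rep_node[s] <- anchor
  }
  clone_nodes <- c(1L, rep_node)
  tree <- phylo_tree(nodes, M)
  deleted <- integer(0)
  del_nodes <- integer(0)
  if (config$n_deletions > 0) {
    for (d in seq_len(config$n_deletions)) {
      S_mat <- node_state_matrix(tree)
      cand_parents <- unique(c(clone_nodes, del_nodes))
      eligible <- lapply(cand_parents, function(v) {
        setdiff(which(S_mat[match(v, tree$id), ] == 1L), deleted)
      })
      ok <- which(lengths(eligible) > 0)
      if (!length(ok)) {
        stop("cannot place deletion ", d,
             ": no node carries an undeleted mutation; reduce n_deletions",
             call. = FALSE)
      }
      pick <- ok[sample.int(length(ok), 1L)]
      mu <- resample(eligible[[pick]], 1L)
      nodes <- tibble::add_row(tibble::as_tibble(tree), id = next_id,
                               parent = cand_parents[pick], type = "loss",
                               mutation = mu, copy = 1L)
      del_nodes <- c(del_nodes, next_id)
      deleted <- c(deleted, mu)
      next_id <- next_id + 1L
      tree <- phylo_tree(nodes, M)
    }
  }
  attr(tree, "clone_nodes") <- c(clone_nodes, del_nodes)
  tree
}

# sample() with safe behavior for length-1 x
resample <- function(x, size) x[sample.int(length(x), size)]

#' Attach cells to a clonal tree
#'
#' Draws each cell's node independently and uniformly with replacement over
#' the tree's clone-level nodes (germline, subclones and deletion nodes
#' alike; the `"clone_nodes"` attribute set by [generate_clonal_tree()], or
#' every node when absent) and derives genotypes from the node states.
#'
#' Uses the current RNG state; seed upstream.
#'
#' @param tree a [phylo_tree()].
#' @param n_cells number of cells to draw.
#' @return a list with `attachment` (a [cell_attachment()]) and `genotypes`
#'   (complete binary matrix).
#' @export
sample_cells <- function(tree, n_cells) {
  pool <- attr(tree, "clone_nodes")
  if (is.null(pool)) pool <- tree$id
  node <- if (n_cells > 0) pool[sample.int(length(pool), n_cells, replace = TRUE)]
          else integer(0)
  att <- cell_attachment(node)
  list(attachment = att, genotypes = genotype_matrix(tree, att))
}

#' Add observation noise to true genotypes
#'
#' Independently per entry: a true 1 flips to 0 with probability `alpha`
#' (false negative), a true 0 flips to 1 with probability `beta` (false
#' positive); afterwards the entry is masked as missing with probability
#' `gamma`. Masking last means every entry is equally likely to go missing
#' regardless of its value.
#'
#' Uses the current RNG state; seed upstream.
#'
#' @param truth complete binary matrix.
#' @param alpha,beta,gamma error and missing probabilities.
#' @return an [scs_matrix()].
#' @export
add_noise <- function(truth, alpha, beta, gamma) {
  n <- nrow(truth); m <- ncol(truth)
  obs <- truth
  if (n * m > 0) {
    flip <- matrix(stats::runif(n * m), n, m)
    obs[truth == 1L & flip < alpha] <- 0L
    obs[truth == 0L & flip < beta] <- 1L
    miss <- matrix(stats::runif(n * m), n, m) < gamma
    obs[miss] <- NA_integer_
  }
  scs_matrix(obs)
}

#' Simulate a noisy single-cell dataset
#'
#' Composes [generate_clonal_tree()], [sample_cells()] and [add_noise()]
#' into a reproducible bundle: ground-truth tree, true cell attachments and
#' genotypes, and the noisy incomplete observed matrix.
#'
#' @param config a [sim_config()]; its `seed` (when non-`NULL`) makes the
#'   bundle fully reproducible.
#' @return a `simulation_bundle` list with `truth_tree`,
#'   `truth_attachment`, `truth_matrix`, `observed` and `config`.
#' @export
simulate_scs <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- generate_clonal_tree(config)
  cells <- sample_cells(tree, config$n_cells)
  observed <- add_noise(cells$genotypes, config$alpha, config$beta, config$gamma)
  stopifnot(is_dollo_1(tree))
  structure(list(truth_tree = tree, truth_attachment = cells$attachment,
                 truth_matrix = cells$genotypes, observed = observed,
                 config = config),
            class = "simulation_bundle")
}

#' @export
print.simulation_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_bundle: %d cells x %d mutations, %d subclones, ",
    "%d deletions, alpha %g, beta %g, gamma %g>\n"),
    x$config$n_cells, x$config$n_mutations, x$config$n_subclones,
    sum(x$truth_tree$type == "loss"), x$config$alpha, x$config$beta,
    x$config$gamma))
  invisible(x)
}
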