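#' Hill-climbing configuration
#'
#' The refinement phase samples `neighbor_samples` random
#' subtree-prune-and-reattach neighbors of the current tree per iteration
#' (the full neighborhood is quadratic in the tree size, which is too large
#' to scan), keeps the best strictly improving one, and stops after
#' `max_iterations` iterations.
#'
#' @param neighbor_samples neighbors drawn per iteration (>= 1).
#' @param max_iterations iterations before stopping (>= 0; 0 returns the
#'   start unchanged).
#' @param seed optional integer seed for the neighbor sampling.
#' @return a `hillclimb_config` list.
#' @export
hillclimb_config <- function(neighbor_samples = 30L, max_iterations = 100L,
                             seed = NULL) {
  stopifnot(neighbor_samples >= 1, max_iterations >= 0)
  structure(list(neighbor_samples = as.integer(neighbor_samples),
                 max_iterations = as.integer(max_iterations),
                 seed = seed),
            class = "hillclimb_config")
}

subtree_ids <- function(tree, u) {
  kids <- children_of(tree)
  out <- integer(0)
  stack <- u
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[v]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

# remove loss nodes that no longer apply: walking down from the root with the
# running per-mutation state, a loss node is kept only when its mutation is
# present in its parent's state; otherwise it is contracted (children are
# re-attached to its parent), which cascades correctly in one pass
contract_invalid_losses <- function(tree) {
  kids <- children_of(tree)
  row_of <- integer(max(tree$id)); row_of[tree$id] <- seq_len(nrow(tree))
  m <- attr(tree, "n_mutations")
  keep <- rep(TRUE, nrow(tree))
  new_parent <- tree$parent
  visit <- function(v, parent_id, state) {
    r <- row_of[v]
    ty <- tree$type[r]
    if (ty == "loss" && state[tree$mutation[r]] == 0L) {
      keep[r] <<- FALSE
      ch <- kids[[v]]
      for (w in if (is.null(ch)) integer(0) else sort(ch)) visit(w, parent_id, state)
      return(invisible())
    }
    new_parent[r] <<- parent_id
    if (ty == "gain") state[tree$mutation[r]] <- 1L
    if (ty == "loss") state[tree$mutation[r]] <- 0L
    ch <- kids[[v]]
    for (w in if (is.null(ch)) integer(0) else sort(ch)) visit(w, v, state)
    invisible()
  }
  visit(tree_root_id(tree), NA_integer_, integer(m))
  nodes <- tree[keep, ]
  nodes$parent <- new_parent[keep]
  phylo_tree(nodes, m, attr(tree, "mutation_labels"))
}

#' Subtree prune and reattach
#'
#' Detaches the subtree rooted at `u` and reattaches it as a child of `v`.
#' Loss nodes invalidated by the move — their mutation is no longer acquired
#' above them, or another loss of the same mutation now precedes them — are
#' contracted (removed, children joined to the parent), so the result is
#' always a valid Dollo(k) tree. Contraction is checked tree-wide, not only
#' inside the moved subtree.
#'
#' @param tree a [phylo_tree()].
#' @param u id of a non-root node (subtree to move).
#' @param v id of the new parent; must not lie in the subtree of `u` and
#'   must differ from `u`'s current parent.
#' @return a new [phylo_tree()].
#' @export
spr_move <- function(tree, u, v) {
  row_of <- match(c(u, v), tree$id)
  if (anyNA(row_of)) stop("invalid SPR move: unknown node id", call. = FALSE)
  ru <- row_of[1]
  if (tree$type[ru] == "root") stop("invalid SPR move: u is the root", call. = FALSE)
  if (v %in% subtree_ids(tree, u))
    stop("invalid SPR move: v lies in the subtree of u", call. = FALSE)
  if (identical(tree$parent[ru], as.integer(v)))
    stop("invalid SPR move: v is already the parent of u", call. = FALSE)
  nodes <- tree
  nodes$parent[ru] <- as.integer(v)
  contract_invalid_losses(
    phylo_tree(nodes, attr(tree, "n_mutations"), attr(tree, "mutation_labels")))
}

valid_spr_pairs <- function(tree) {
  non_root <- tree$id[tree$type != "root"]
  pairs <- list()
  for (u in non_root) {
    sub <- subtree_ids(tree, u)
    pu <- tree$parent[match(u, tree$id)]
    vs <- setdiff(tree$id, c(sub, pu))
    if (length(vs)) pairs[[length(pairs) + 1L]] <- cbind(u, vs)
  }
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  do.call(rbind, pairs)
}

#' Draw one random SPR neighbor
#'
#' Picks (u, v) uniformly among the valid SPR moves of the tree and applies
#' [spr_move()]. If no valid move exists (e.g. a two-node tree) the input
#' tree is returned unchanged.
#'
#' @param tree a [phylo_tree()].
#' @return a [phylo_tree()].
#' @export
sample_neighbor <- function(tree) {
  pairs <- valid_spr_pairs(tree)
  if (nrow(pairs) == 0) return(tree)
  i <- sample.int(nrow(pairs), 1L)
  spr_move(tree, pairs[i, 1], pairs[i, 2])
}

#' Hill climbing over SPR neighborhoods
#'
#' Starting from a Dollo(k) tree, each iteration scores
#' `config$neighbor_samples` random SPR neighbors by their best cell
#' attachment likelihood; if the best neighbor strictly improves the current
#' score the search moves there (plateaus do not move). The best tree,
#' attachment and likelihood ever evaluated are returned, so the result is
#' never worse than the start.
#'
#' @param start a [phylo_tree()] (typically the solver's tree).
#' @param I an [scs_matrix()].
#' @param rates an [error_rates()] object.
#' @param config a [hillclimb_config()].
#' @return a list with `tree`, `attachment`, `log_likelihood`, and `trace`
#'   (a tibble of per-iteration current/best scores).
#' @export
hill_climb <- function(start, I, rates, config = hillclimb_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cur_tree <- start
  cur <- best_attachment(cur_tree, I, rates)
  best <- list(tree = cur_tree, attachment = cur$attachment,
               log_likelihood = cur$log_likelihood)
  trace <- vector("list", config$max_iterations)
  if (config$max_iterations > 0) {
    for (it in seq_len(config$max_iterations)) {
      cand_best <- NULL
      for (s in seq_len(config$neighbor_samples)) {
        nb <- sample_neighbor(cur_tree)
        sc <- best_attachment(nb, I, rates)
        if (is.null(cand_best) || sc$log_likelihood > cand_best$log_likelihood) {
          cand_best <- list(tree = nb, attachment = sc$attachment,
                            log_likelihood = sc$log_likelihood)
        }
      }
      if (!is.null(cand_best) &&
          cand_best$log_likelihood > cur$log_likelihood) {
        cur_tree <- cand_best$tree
        cur <- cand_best[c("attachment", "log_likelihood")]
        if (cand_best$log_likelihood > best$log_likelihood) best <- cand_best
      }
      trace[[it]] <- tibble::tibble(iteration = it,
                                    current = cur$log_likelihood,
                                    best = best$log_likelihood)
    }
  }
  best$trace <- dplyr::bind_rows(trace)
  best
}
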