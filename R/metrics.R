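#' Classify mutation pairs by their tree relationship
#'
#' Looks only at gain nodes (losses do not enter the accuracy measures).
#' An ordered pair (x, y) is ancestor-descendant (AD) when the gain of x is
#' a proper ancestor of the gain of y; an unordered pair is
#' different-lineage (DL) when neither gain is an ancestor of the other;
#' pairs gained at the same node would be classified `same_node` (this
#' package's trees carry one label per node, so the class arises only for
#' trees from external sources).
#'
#' @param tree a [phylo_tree()] in which every mutation has a gain node.
#' @return a list with `ad_pairs` (2-column matrix of ordered pairs),
#'   `dl_pairs` and `same_node_pairs` (2-column matrices of unordered pairs
#'   with x < y).
#' @export
classify_pairs <- function(tree) {
  m <- attr(tree, "n_mutations")
  gain_node <- rep(NA_integer_, m)
  gains <- tree$type == "gain"
  gain_node[tree$mutation[gains]] <- tree$id[gains]
  # mutations without a gain node (possible in trees imported from other
  # tools) enter no pair set: their truth pairs then count as unpreserved
  # ancestor sets via root paths
  parent_of <- tree$parent[match(tree$id, tree$id)]
  names(parent_of) <- tree$id
  path_of <- function(v) {
    out <- integer(0)
    while (!is.na(v)) {
      out <- c(out, v)
      v <- parent_of[[as.character(v)]]
    }
    out
  }
  paths <- lapply(gain_node, function(v) if (is.na(v)) integer(0) else path_of(v))
  ad <- matrix(integer(0), 0, 2)
  dl <- matrix(integer(0), 0, 2)
  same <- matrix(integer(0), 0, 2)
  if (m >= 2) {
    for (x in seq_len(m - 1L)) {
      for (y in seq((x + 1L), m)) {
        if (is.na(gain_node[x]) || is.na(gain_node[y])) {
          next
        } else if (gain_node[x] == gain_node[y]) {
          same <- rbind(same, c(x, y))
        } else if (gain_node[x] %in% paths[[y]][-1]) {
          ad <- rbind(ad, c(x, y))
        } else if (gain_node[y] %in% paths[[x]][-1]) {
          ad <- rbind(ad, c(y, x))
        } else {
          dl <- rbind(dl, c(x, y))
        }
      }
    }
  }
  list(ad_pairs = ad, dl_pairs = dl, same_node_pairs = same)
}

pair_key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)

f_measure_sets <- function(truth_keys, inferred_keys) {
  tp <- length(intersect(truth_keys, inferred_keys))
  precision <- if (length(inferred_keys) == 0) {
    if (length(truth_keys) == 0) 1 else 0
  } else tp / length(inferred_keys)
  recall <- if (length(truth_keys) == 0) {
    if (length(inferred_keys) == 0) 1 else 0
  } else tp / length(truth_keys)
  if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
}

check_mutation_sets <- function(truth, inferred) {
  mt <- attr(truth, "n_mutations")
  mi <- attr(inferred, "n_mutations")
  inf_muts <- unique(inferred$mutation[inferred$type == "gain"])
  if (any(inf_muts > mt)) {
    stop("mutation-set mismatch: inferred tree contains mutations absent ",
         "from the truth tree", call. = FALSE)
  }
  invisible(TRUE)
}

#' Ancestor-descendant accuracy
#'
#' F-measure (balanced F1) of the ordered ancestor-descendant mutation
#' pairs of the truth tree that are preserved in the inferred tree:
#' precision is the preserved fraction of the inferred AD pairs, recall the
#' preserved fraction of the truth AD pairs. Pairs gained at the same node
#' belong to neither the AD nor the DL universe. With an empty denominator,
#' precision/recall is 1 when the other set is empty too, else 0.
#'
#' @param truth,inferred [phylo_tree()] objects over the same mutation set.
#' @return a score in `[0, 1]`.
#' @export
ad_f_measure <- function(truth, inferred) {
  check_mutation_sets(truth, inferred)
  f_measure_sets(pair_key(classify_pairs(truth)$ad_pairs),
                 pair_key(classify_pairs(inferred)$ad_pairs))
}

#' Different-lineage accuracy
#'
#' F-measure of the unordered different-lineage (neither mutation ancestral
#' to the other) pairs of the truth tree preserved in the inferred tree;
#' conventions as in [ad_f_measure()].
#'
#' @param truth,inferred [phylo_tree()] objects over the same mutation set.
#' @return a score in `[0, 1]`.
#' @export
dl_f_measure <- function(truth, inferred) {
  check_mutation_sets(truth, inferred)
  f_measure_sets(pair_key(classify_pairs(truth)$dl_pairs),
                 pair_key(classify_pairs(inferred)$dl_pairs))
}

#' Compare an inferred tree with the ground truth
#'
#' @param truth,inferred [phylo_tree()] objects over the same mutation set.
#' @return a one-row tibble with `ad_f` and `dl_f`.
#' @export
evaluate_trees <- function(truth, inferred) {
  tibble::tibble(ad_f = ad_f_measure(truth, inferred),
                 dl_f = dl_f_measure(truth, inferred))
}
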