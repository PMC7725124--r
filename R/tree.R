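#' Mutation-labeled phylogenies
#'
#' A `phylo_tree` is a rooted tree whose non-root nodes are each labeled by a
#' single mutation gain or loss. The unlabeled root is the germline. The
#' node table is a tibble with columns `id` (unique integer, root is always
#' 1), `parent` (`NA` for the root), `type` (`"root"`, `"gain"` or
#' `"loss"`), `mutation` (1-based index, `NA` for the root) and `copy` (loss
#' copy number, `NA` otherwise).
#'
#' Under the Dollo(k) model a valid tree has at most one gain node per
#' mutation, every loss node of a mutation lies strictly below its gain, and
#' no two losses of the same mutation are nested on one root path.
#'
#' @param nodes a data frame as described above.
#' @param n_mutations number of mutations in the underlying problem.
#' @param mutation_labels optional character labels (default `mut1...`).
#' @return a `phylo_tree` object (a tibble with extra attributes).
#' @export
phylo_tree <- function(nodes, n_mutations, mutation_labels = NULL) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("id", "parent", "type", "mutation", "copy") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$mutation <- as.integer(nodes$mutation)
  nodes$copy <- as.integer(nodes$copy)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (sum(nodes$type == "root") != 1 || !is.na(nodes$parent[nodes$type == "root"]))
    stop("phylo_tree needs exactly one root with NA parent", call. = FALSE)
  if (is.null(mutation_labels)) mutation_labels <- default_labels("mut", n_mutations)
  stopifnot(length(mutation_labels) == n_mutations)
  structure(nodes, n_mutations = as.integer(n_mutations),
            mutation_labels = mutation_labels,
            class = c("phylo_tree", class(tibble::tibble())))
}

#' A root-only tree
#' @param n_mutations number of mutations in the underlying problem.
#' @param mutation_labels optional labels.
#' @return a [phylo_tree()] with a single germline node.
#' @export
root_tree <- function(n_mutations, mutation_labels = NULL) {
  phylo_tree(tibble::tibble(id = 1L, parent = NA_integer_, type = "root",
                            mutation = NA_integer_, copy = NA_integer_),
             n_mutations, mutation_labels)
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat(sprintf("<phylo_tree: %d nodes (%d gains, %d losses), %d mutations>\n",
              nrow(x), sum(x$type == "gain"), sum(x$type == "loss"),
              attr(x, "n_mutations")))
  NextMethod()
}

tree_root_id <- function(tree) tree$id[tree$type == "root"]

# children list indexed by node id (list position = id)
children_of <- function(tree) {
  kids <- split(tree$id[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
  out <- vector("list", max(tree$id))
  out[as.integer(names(kids))] <- kids
  out
}

# ids in depth-first preorder from the root; children visited in id order
preorder_ids <- function(tree) {
  kids <- children_of(tree)
  out <- integer(nrow(tree))
  stack <- tree_root_id(tree)
  i <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    i <- i + 1L
    out[i] <- v
    ch <- kids[[v]]
    if (!is.null(ch) && length(ch)) stack <- c(stack, rev(sort(ch)))
  }
  out[seq_len(i)]
}

# binary state matrix: one row per node (in tree row order), cols = mutations
node_state_matrix <- function(tree) {
  m <- attr(tree, "n_mutations")
  row_of <- integer(max(tree$id)); row_of[tree$id] <- seq_len(nrow(tree))
  S <- matrix(0L, nrow(tree), m)
  for (v in preorder_ids(tree)) {
    r <- row_of[v]
    p <- tree$parent[r]
    if (!is.na(p)) S[r, ] <- S[row_of[p], ]
    if (tree$type[r] == "gain") S[r, tree$mutation[r]] <- 1L
    if (tree$type[r] == "loss") S[r, tree$mutation[r]] <- 0L
  }
  rownames(S) <- tree$id
  S
}

#' State of a tree node
#'
#' The set of mutations acquired and not subsequently lost on the path from
#' the root to the node; a cell attached at the node is predicted to carry
#' exactly this set.
#'
#' @param tree a [phylo_tree()].
#' @param node a node id.
#' @return sorted integer vector of mutation indices.
#' @export
node_state <- function(tree, node) {
  if (!node %in% tree$id) stop("unknown node id: ", node, call. = FALSE)
  S <- node_state_matrix(tree)
  which(S[match(node, tree$id), ] == 1L)
}

#' Extract a phylogeny from a conflict-free extended matrix
#'
#' The classic directed perfect-phylogeny construction applied to the
#' nonzero columns of the completed extended matrix: columns are sorted by
#' decreasing number of 1s (ties broken by original column order), identical
#' columns share one edge (realized as a chain of single-label nodes in
#' column order), all-zero columns are omitted, and each matrix row maps to
#' the node whose root path carries exactly the row's 1-entries.
#'
#' @param E a conflict-free [extended_matrix()].
#' @param mutation_labels optional labels for the original mutations.
#' @return a [phylo_tree()]; the row-to-node mapping is attached as
#'   attribute `"row_nodes"` (integer node id per matrix row).
#' @export
tree_from_extended_matrix <- function(E, mutation_labels = NULL) {
  if (!is_conflict_free(E)) {
    stop("extended matrix has conflicting columns; no perfect phylogeny exists",
         call. = FALSE)
  }
  n_mut <- attr(E, "n_mutations")
  cols <- attr(E, "columns")
  M <- unclass(E)
  counts <- colSums(M)
  keep <- which(counts > 0)
  # sort kept columns by decreasing count, ties by original column order
  ord <- keep[order(-counts[keep], keep)]
  nodes <- tibble::tibble(id = 1L, parent = NA_integer_, type = "root",
                          mutation = NA_integer_, copy = NA_integer_)
  next_id <- 2L
  chain_last <- integer(0)   # per distinct column group: last node id
  group_of <- integer(length(ord))  # sorted position -> group index
  group_cols <- list()       # group index -> sorted positions of its columns
  # group identical columns (consecutive in the sorted order only if counts
  # equal; identical columns always have equal counts so scan globally)
  key <- vapply(ord, function(j) paste(M[, j], collapse = ""), character(1))
  groups <- match(key, unique(key))
  n_groups <- max(0L, groups)
  group_members <- split(seq_along(ord), groups)
  # representative (first sorted position) per group, in sorted order
  reps <- vapply(group_members, `[`, integer(1), 1L)
  grp_order <- order(reps)
  # parent group of each group: deepest earlier group whose column contains it
  first_one <- function(j) which(M[, j] == 1L)
  grp_col <- vapply(group_members, function(ix) ord[ix[1]], integer(1))
  grp_first <- integer(length(group_members))  # first node id of group chain
  grp_last <- integer(length(group_members))
  for (gi in grp_order) {
    j <- grp_col[gi]
    rows1 <- which(M[, j] == 1L)
    # parent column: the latest group, earlier in sorted order, whose column
    # has a 1 in these rows (conflict-freedom makes the choice consistent)
    parent_node <- 1L
    best_rep <- -1L
    for (gj in grp_order) {
      if (reps[gj] >= reps[gi]) break
      jj <- grp_col[gj]
      if (all(M[rows1, jj] == 1L)) {
        if (reps[gj] > best_rep) { best_rep <- reps[gj]; parent_node <- grp_last[gj] }
      } else if (any(M[rows1, jj] == 1L)) {
        stop("internal error: conflicting columns survived the conflict test")
      }
    }
    # build the chain of labels for this group, in original column order
    members <- sort(ord[group_members[[gi]]])
    prev <- parent_node
    for (j2 in members) {
      nodes <- tibble::add_row(nodes, id = next_id, parent = prev,
                               type = cols$type[j2], mutation = cols$mutation[j2],
                               copy = cols$copy[j2])
      prev <- next_id
      if (j2 == members[1]) grp_first[gi] <- next_id
      next_id <- next_id + 1L
    }
    grp_last[gi] <- prev
  }
  tree <- phylo_tree(nodes, n_mut, mutation_labels)
  # map rows to nodes: the deepest (latest sorted) column with a 1; rows with
  # no 1s map to the root
  row_nodes <- rep(1L, nrow(M))
  if (length(ord)) {
    sorted_pos <- seq_along(ord)
    for (r in seq_len(nrow(M))) {
      ones <- which(M[r, ord] == 1L)
      if (length(ones)) {
        gi <- groups[max(ones)]
        row_nodes[r] <- grp_last[gi]
      }
    }
  }
  attr(tree, "row_nodes") <- row_nodes
  tree
}

#' Cell attachments
#'
#' A total mapping from cells to tree nodes, as a tibble with columns `cell`
#' and `node`.
#'
#' @param node integer vector of node ids, one per cell in order.
#' @return a `cell_attachment` tibble.
#' @export
cell_attachment <- function(node) {
  structure(tibble::tibble(cell = seq_along(node), node = as.integer(node)),
            class = c("cell_attachment", class(tibble::tibble())))
}

#' Genotypes implied by a tree and an attachment
#'
#' Row `c` of the result is the binary state of the node cell `c` is
#' attached to.
#'
#' @param tree a [phylo_tree()].
#' @param attachment a [cell_attachment()] covering all cells.
#' @return a complete binary matrix, cells x mutations.
#' @export
genotype_matrix <- function(tree, attachment) {
  S <- node_state_matrix(tree)
  idx <- match(attachment$node, tree$id)
  if (anyNA(idx)) stop("attachment refers to unknown node ids", call. = FALSE)
  G <- S[idx, , drop = FALSE]
  rownames(G) <- NULL
  G
}

#' Maximum-likelihood cell attachment
#'
#' Attaches every cell independently to the node whose state maximizes the
#' cell's summed entry log-probabilities; ties go to the smallest node id.
#' Because cells are independent, per-cell optimality gives the global
#' optimum over attachments for the fixed tree.
#'
#' @param tree a [phylo_tree()].
#' @param I an [scs_matrix()].
#' @param rates an [error_rates()] object.
#' @return a list with `attachment` (a [cell_attachment()]) and
#'   `log_likelihood` (total over cells).
#' @export
best_attachment <- function(tree, I, rates) {
  S <- node_state_matrix(tree)
  co <- objective_coefficients(I, rates)
  # score[c, v] = sum_m slope[c,m] * S[v,m] + sum_m intercept[c,m]
  scores <- co$slope %*% t(S)
  # order node columns by id so that which.max tie-breaks on smallest id
  ord <- order(tree$id)
  scores <- scores[, ord, drop = FALSE]
  pick <- apply(scores, 1, which.max)
  node <- tree$id[ord][pick]
  ll <- sum(scores[cbind(seq_len(nrow(I)), pick)]) + sum(co$intercept)
  list(attachment = cell_attachment(node), log_likelihood = ll)
}

#' Dollo(k) validity of a labeled tree
#'
#' Checks that each mutation has at most one gain node and at most `k` loss
#' nodes, that every loss lies strictly below its mutation's gain, and that
#' no other loss of the same mutation lies between them on the root path.
#'
#' @param tree a [phylo_tree()].
#' @param k allowed losses per mutation.
#' @return `TRUE` iff the tree is a valid Dollo(k) phylogeny.
#' @export
is_dollo_k <- function(tree, k) {
  gains <- table(tree$mutation[tree$type == "gain"])
  if (any(gains > 1)) return(FALSE)
  losses <- table(tree$mutation[tree$type == "loss"])
  if (any(losses > k)) return(FALSE)
  # walk down tracking per-mutation presence; a loss node is valid only if
  # its mutation is currently present at its parent
  S <- node_state_matrix(tree)
  row_of <- match(tree$id, tree$id)
  loss_rows <- which(tree$type == "loss")
  for (r in loss_rows) {
    p <- tree$parent[r]
    ps <- S[match(p, tree$id), tree$mutation[r]]
    if (ps != 1L) return(FALSE)
  }
  TRUE
}

#' Shorthand for [is_dollo_k()] with `k = 1`
#' @param tree a [phylo_tree()].
#' @export
is_dollo_1 <- function(tree) is_dollo_k(tree, 1L)

node_display_label <- function(tree, r) {
  labs <- attr(tree, "mutation_labels")
  if (tree$type[r] == "root") return("germline")
  base <- labs[tree$mutation[r]]
  if (tree$type[r] == "gain") base
  else if (is.na(tree$copy[r]) || tree$copy[r] == 1L) paste0(base, "-")
  else paste0(base, "-(", tree$copy[r], ")")
}

#' DOT export of a phylogeny
#'
#' Emits a Graphviz digraph. Loss (deletion) nodes are drawn red, following
#' the usual rendering convention for mutation losses. With
#' `collapse_linear_paths = TRUE`, chains of out-degree-1 nodes are merged
#' into a single display node listing all labels (display only; the
#' underlying tree is unchanged). Node attributes carry a machine-readable
#' `comment` so that uncollapsed output can be parsed back by
#' [read_dot_tree()].
#'
#' @param tree a [phylo_tree()].
#' @param attachment optional [cell_attachment()]; attached cell counts are
#'   appended to node labels.
#' @param collapse_linear_paths merge linear chains for display.
#' @return a single string of DOT text.
#' @export
to_dot <- function(tree, attachment = NULL, collapse_linear_paths = FALSE) {
  kids <- children_of(tree)
  row_of <- integer(max(tree$id)); row_of[tree$id] <- seq_len(nrow(tree))
  counts <- NULL
  if (!is.null(attachment)) counts <- table(attachment$node)
  lab_of <- function(ids) {
    paste(vapply(ids, function(v) node_display_label(tree, row_of[v]), character(1)),
          collapse = "\\n")
  }
  groups <- list()
  if (collapse_linear_paths) {
    # group maximal chains of out-degree-1, in-"chain" nodes
    visited <- logical(max(tree$id))
    for (v in preorder_ids(tree)) {
      if (visited[v]) next
      chain <- v
      visited[v] <- TRUE
      repeat {
        ch <- kids[[chain[length(chain)]]]
        if (is.null(ch) || length(ch) != 1) break
        nxt <- ch[1]
        if (tree$type[row_of[nxt]] == "root") break
        chain <- c(chain, nxt)
        visited[nxt] <- TRUE
      }
      groups[[length(groups) + 1L]] <- chain
    }
  } else {
    groups <- as.list(tree$id)
  }
  grp_of <- integer(max(tree$id))
  for (gi in seq_along(groups)) grp_of[groups[[gi]]] <- gi
  lines <- c("digraph phylogeny {", "  node [shape=box];")
  for (gi in seq_along(groups)) {
    ids <- groups[[gi]]
    r1 <- row_of[ids[1]]
    has_loss <- any(tree$type[row_of[ids]] == "loss")
    lab <- lab_of(ids)
    if (!is.null(counts)) {
      ncells <- sum(counts[as.character(ids)], na.rm = TRUE)
      if (ncells > 0) lab <- paste0(lab, "\\n(", ncells, " cells)")
    }
    meta <- paste(vapply(ids, function(v) {
      r <- row_of[v]
      sprintf("%d:%s:%s:%s", v, tree$type[r],
              ifelse(is.na(tree$mutation[r]), "NA", tree$mutation[r]),
              ifelse(is.na(tree$copy[r]), "NA", tree$copy[r]))
    }, character(1)), collapse = ";")
    style <- if (has_loss) ", color=red, fontcolor=red" else ""
    lines <- c(lines, sprintf('  n%d [label="%s", comment="%s"%s];',
                              ids[1], lab, meta, style))
  }
  for (r in seq_len(nrow(tree))) {
    v <- tree$id[r]; p <- tree$parent[r]
    if (is.na(p)) next
    if (grp_of[v] == grp_of[p]) next  # internal chain edge, collapsed
    # draw from the group head of the parent's group to this group head
    if (groups[[grp_of[v]]][1] != v) next
    lines <- c(lines, sprintf("  n%d -> n%d;", groups[[grp_of[p]]][1], v))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Write a tree as DOT
#' @param tree a [phylo_tree()].
#' @param path output path (conventionally `.gv`).
#' @param ... passed to [to_dot()].
#' @return `path`, invisibly.
#' @export
write_dot_tree <- function(tree, path, ...) {
  writeLines(to_dot(tree, ...), path)
  invisible(path)
}

#' Read back a DOT tree written by this package
#'
#' Parses uncollapsed DOT output of [to_dot()] (using the machine-readable
#' `comment` attributes) back into a [phylo_tree()]. Intended for the
#' `evaluate` workflow, which compares trees saved as `.gv` files.
#'
#' @param path path to a DOT file produced by [write_dot_tree()].
#' @param n_mutations number of mutations; defaults to the largest mutation
#'   index present.
#' @return a [phylo_tree()].
#' @export
read_dot_tree <- function(path, n_mutations = NULL) {
  lines <- readLines(path)
  node_re <- '^\\s*n(\\d+)\\s*\\[.*comment="([^"]*)"'
  edge_re <- "^\\s*n(\\d+)\\s*->\\s*n(\\d+)\\s*;"
  nodes <- list()
  edges <- list()
  for (l in lines) {
    mn <- regmatches(l, regexec(node_re, l))[[1]]
    if (length(mn) == 3) {
      for (part in strsplit(mn[3], ";", fixed = TRUE)[[1]]) {
        f <- strsplit(part, ":", fixed = TRUE)[[1]]
        nodes[[length(nodes) + 1L]] <- tibble::tibble(
          id = as.integer(f[1]), type = f[2],
          mutation = suppressWarnings(as.integer(f[3])),
          copy = suppressWarnings(as.integer(f[4])))
      }
      next
    }
    me <- regmatches(l, regexec(edge_re, l))[[1]]
    if (length(me) == 3) {
      edges[[length(edges) + 1L]] <- c(as.integer(me[2]), as.integer(me[3]))
    }
  }
  nd <- dplyr::bind_rows(nodes)
  if (!nrow(nd)) stop("no nodes found in DOT file '", path, "'", call. = FALSE)
  parent <- rep(NA_integer_, nrow(nd))
  names(parent) <- nd$id
  for (e in edges) parent[as.character(e[2])] <- e[1]
  nd$parent <- unname(parent[as.character(nd$id)])
  if (is.null(n_mutations)) n_mutations <- max(0L, nd$mutation, na.rm = TRUE)
  phylo_tree(nd[, c("id", "parent", "type", "mutation", "copy")], n_mutations)
}
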