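# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: likelihoods by explicit double loops over the
# conditional table, tree optima by exhaustive enumeration of all Dollo(1)
# phylogenies at tiny size, pair classification by subtree membership.

# --- likelihood oracle: explicit double loop over the conditional table ----

oracle_log_likelihood <- function(I, F, alpha, beta) {
  alpha <- min(max(alpha, 1e-9), 1 - 1e-9)
  beta <- min(max(beta, 1e-9), 1 - 1e-9)
  ll <- 0
  for (c in seq_len(nrow(I))) {
    for (j in seq_len(ncol(I))) {
      o <- I[c, j]
      if (is.na(o)) next
      p <- if (F[c, j] == 1) {
        if (o == 1) 1 - alpha else alpha
      } else {
        if (o == 1) beta else 1 - beta
      }
      ll <- ll + log(p)
    }
  }
  ll
}

# --- exhaustive Dollo(1) optimum at tiny size ------------------------------

# Enumerate every rooted labeled tree over m gain nodes plus one loss node
# per mutation in a chosen subset, requiring each loss to sit strictly below
# its gain.  What matters for attachment likelihoods is only the set of node
# states, so trees are collapsed to distinct "state families" (sets of
# m-bit genotype masks, always containing the empty root state).
dollo1_state_families <- local({
  cache <- list()
  function(m) {
    key <- as.character(m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fam <- new.env(parent = emptyenv())
    for (loss_mask in 0:(2^m - 1)) {
      loss_muts <- which(bitwAnd(loss_mask, bitwShiftL(1L, 0:(m - 1))) > 0)
      q <- m + length(loss_muts)   # non-root nodes: gains 1..m, then losses
      node_mut <- c(seq_len(m), loss_muts)
      is_loss <- c(rep(FALSE, m), rep(TRUE, length(loss_muts)))
      # enumerate parent vectors: parent of node i is 0 (root) or another node
      parent <- integer(q)
      recurse <- function(i) {
        if (i > q) {
          # acyclicity + depth via iterative resolution
          depth <- rep(NA_integer_, q)
          get_depth <- function(v, seen = integer(0)) {
            if (v == 0) return(0L)
            if (v %in% seen) return(NA_integer_)
            if (!is.na(depth[v])) return(depth[v])
            d <- get_depth(parent[v], c(seen, v))
            if (is.na(d)) return(NA_integer_)
            depth[v] <<- d + 1L
            depth[v]
          }
          for (v in seq_len(q)) if (is.na(get_depth(v))) return(invisible())
          # ancestor test by climbing
          is_anc <- function(a, b) {
            v <- parent[b]
            while (v != 0) {
              if (v == a) return(TRUE)
              v <- parent[v]
            }
            FALSE
          }
          for (li in which(is_loss)) {
            if (!is_anc(node_mut[li], li)) return(invisible())
          }
          # state masks: root plus every node
          masks <- 0L
          for (v in seq_len(q)) {
            mask <- 0L
            u <- v
            gained <- integer(0); lost <- integer(0)
            while (u != 0) {
              if (is_loss[u]) lost <- c(lost, node_mut[u])
              else gained <- c(gained, node_mut[u])
              u <- parent[u]
            }
            present <- setdiff(gained, lost)
            if (length(present)) mask <- sum(bitwShiftL(1L, present - 1L))
            masks <- c(masks, mask)
          }
          fam_key <- paste(sort(unique(masks)), collapse = ",")
          assign(fam_key, TRUE, envir = fam)
          return(invisible())
        }
        for (p in 0:q) {
          if (p == i) next
          parent[i] <<- p
          recurse(i + 1)
        }
      }
      recurse(1L)
    }
    out <- lapply(ls(fam), function(k) as.integer(strsplit(k, ",")[[1]]))
    cache[[key]] <<- out
    out
  }
})

# maximum log-likelihood over all Dollo(1) phylogenies with free per-cell
# attachment, by exhaustive enumeration
oracle_dollo1_optimum <- function(I, alpha, beta) {
  m <- ncol(I)
  families <- dollo1_state_families(m)
  n <- nrow(I)
  # log-likelihood of each cell against each of the 2^m genotypes
  cell_ll <- matrix(0, n, 2^m)
  for (g in 0:(2^m - 1)) {
    geno <- as.integer(bitwAnd(g, bitwShiftL(1L, 0:(m - 1))) > 0)
    Fg <- matrix(geno, n, m, byrow = TRUE)
    for (c in seq_len(n)) {
      cell_ll[c, g + 1] <- oracle_log_likelihood(I[c, , drop = FALSE],
                                                 Fg[c, , drop = FALSE],
                                                 alpha, beta)
    }
  }
  best <- -Inf
  for (masks in families) {
    sc <- sum(apply(cell_ll[, masks + 1, drop = FALSE], 1, max))
    if (sc > best) best <- sc
  }
  best
}

# --- pair-classification oracle via subtree membership ---------------------

oracle_pair_sets <- function(tree) {
  m <- attr(tree, "n_mutations")
  gains <- tree$type == "gain"
  gain_node <- rep(NA_integer_, m)
  gain_node[tree$mutation[gains]] <- tree$id[gains]
  kids <- split(tree$id[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
  desc <- function(v) {
    out <- integer(0)
    stack <- kids[[as.character(v)]]
    while (length(stack)) {
      w <- stack[1]; stack <- stack[-1]
      out <- c(out, w)
      stack <- c(stack, kids[[as.character(w)]])
    }
    out
  }
  ad <- character(0); dl <- character(0); same <- character(0)
  for (x in seq_len(m)) {
    for (y in seq_len(m)) {
      if (x >= y) next
      gx <- gain_node[x]; gy <- gain_node[y]
      if (is.na(gx) || is.na(gy)) next
      if (gx == gy) same <- c(same, paste(x, y))
      else if (gy %in% desc(gx)) ad <- c(ad, paste(x, y))
      else if (gx %in% desc(gy)) ad <- c(ad, paste(y, x))
      else dl <- c(dl, paste(x, y))
    }
  }
  list(ad = ad, dl = dl, same = same)
}

oracle_f_measure <- function(truth_keys, inf_keys) {
  tp <- length(intersect(truth_keys, inf_keys))
  prec <- if (length(inf_keys)) tp / length(inf_keys) else as.numeric(length(truth_keys) == 0)
  rec <- if (length(truth_keys)) tp / length(truth_keys) else as.numeric(length(inf_keys) == 0)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# --- random fixtures -------------------------------------------------------

random_scs <- function(n, m, p_one = 0.4, p_missing = 0.1) {
  v <- sample(c(0L, 1L, NA_integer_), n * m, replace = TRUE,
              prob = c(1 - p_one - p_missing, p_one, p_missing))
  scs_matrix(matrix(v, n, m))
}

# a random Dollo(1) tree via the simulator's generator
random_dollo1_tree <- function(n_mutations = 6, n_subclones = 4, n_deletions = 1) {
  generate_clonal_tree(sim_config(n_subclones = n_subclones,
                                  n_cells = 0, n_mutations = n_mutations,
                                  n_deletions = n_deletions))
}
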