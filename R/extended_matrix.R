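#' Extended gain/loss column space
#'
#' Under the Dollo(k) model each mutation `m` is represented by one gain
#' column `m+` and `k` loss columns `m1-, ..., mk-`. A matrix admits a
#' Dollo(k) phylogeny exactly when the extended matrix admits a conflict-free
#' (directed perfect phylogeny) completion in which, per cell and mutation,
#' the gain entry minus the sum of loss entries reproduces the original
#' entry.
#'
#' `extended_columns()` enumerates the extended column identities in
#' canonical order: for each mutation in original order, its gain column
#' followed by its loss copies `1..k`.
#'
#' @param n_mutations number of original mutations.
#' @param k maximum number of losses per mutation (Dollo parameter).
#' @return a tibble with one row per extended column: `index` (1-based
#'   position), `mutation` (1-based original column), `type` (`"gain"` or
#'   `"loss"`), `copy` (loss copy 1..k, `NA` for gains).
#' @examples
#' extended_columns(2, 1)
#' @export
extended_columns <- function(n_mutations, k) {
  stopifnot(n_mutations >= 0, k >= 0)
  per <- k + 1L
  if (n_mutations == 0) {
    return(tibble::tibble(index = integer(0), mutation = integer(0),
                          type = character(0), copy = integer(0)))
  }
  mutation <- rep(seq_len(n_mutations), each = per)
  slot <- rep(seq_len(per) - 1L, times = n_mutations)
  tibble::tibble(
    index = seq_along(mutation),
    mutation = mutation,
    type = ifelse(slot == 0L, "gain", "loss"),
    copy = ifelse(slot == 0L, NA_integer_, slot)
  )
}

#' Complete binary extended matrix
#'
#' Container for a complete 0/1 matrix over the extended column space of
#' [extended_columns()]. Validates that for every cell and mutation the gain
#' entry minus the summed loss entries lies in `{0, 1}` (a loss is only
#' possible where the mutation was gained, and loss copies are mutually
#' exclusive per cell).
#'
#' @param entries binary matrix, cells x (`n_mutations * (k + 1)`) extended
#'   columns in canonical order.
#' @param n_mutations,k dimensions of the extended column space.
#' @param validate enforce the contraction invariant at construction; set to
#'   `FALSE` to build candidate completions whose validity is to be tested
#'   with [check_dollo_completion()].
#' @return an `extended_matrix` object.
#' @export
extended_matrix <- function(entries, n_mutations, k, validate = TRUE) {
  if (!is.matrix(entries)) entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  cols <- extended_columns(n_mutations, k)
  stopifnot(ncol(entries) == nrow(cols), all(entries %in% c(0L, 1L)))
  contracted <- contract_extended(entries, n_mutations, k)
  if (validate && any(contracted < 0L | contracted > 1L)) {
    stop("invalid extended matrix: gain minus summed losses must be 0 or 1 ",
         "for every cell and mutation", call. = FALSE)
  }
  structure(entries, columns = cols, n_mutations = n_mutations, k = k,
            class = c("extended_matrix", "matrix", "array"))
}

# Gain minus summed losses, per cell and mutation (the Dollo contraction).
contract_extended <- function(entries, n_mutations, k) {
  per <- k + 1L
  gains <- entries[, (seq_len(n_mutations) - 1L) * per + 1L, drop = FALSE]
  losses <- matrix(0L, nrow(entries), n_mutations)
  if (k > 0 && n_mutations > 0) {
    for (l in seq_len(k)) {
      losses <- losses + entries[, (seq_len(n_mutations) - 1L) * per + 1L + l, drop = FALSE]
    }
  }
  gains - losses
}

#' @export
print.extended_matrix <- function(x, ...) {
  cat(sprintf("<extended_matrix: %d cells x %d mutations, k = %d (%d columns)>\n",
              nrow(x), attr(x, "n_mutations"), attr(x, "k"), ncol(x)))
  m <- unclass(x)
  cols <- attr(x, "columns")
  colnames(m) <- ifelse(cols$type == "gain", paste0("m", cols$mutation, "+"),
                        paste0("m", cols$mutation, "-", cols$copy))
  attr(m, "columns") <- NULL; attr(m, "n_mutations") <- NULL; attr(m, "k") <- NULL
  print(m, ...)
  invisible(x)
}

#' Column-pair conflict test
#'
#' Two binary columns are in conflict when rows exhibiting all three
#' configurations (0,1), (1,0) and (1,1) exist — the forbidden submatrix of
#' the directed perfect phylogeny characterization.
#'
#' @param col_p,col_q binary vectors of equal length.
#' @return `TRUE` iff the pair is in conflict.
#' @export
columns_in_conflict <- function(col_p, col_q) {
  if (length(col_p) != length(col_q)) {
    stop("columns_in_conflict: length mismatch", call. = FALSE)
  }
  any(col_p == 0 & col_q == 1) && any(col_p == 1 & col_q == 0) &&
    any(col_p == 1 & col_q == 1)
}

#' Conflict-freedom of a complete binary matrix
#'
#' A complete binary matrix admits a directed perfect phylogeny iff no
#' unordered pair of columns is in conflict. Configuration counts for all
#' pairs are obtained by three crossproducts.
#'
#' @param E a binary matrix (an [extended_matrix()] or plain 0/1 matrix).
#' @return `TRUE` iff no pair of columns conflicts.
#' @export
is_conflict_free <- function(E) {
  M <- unclass(E)
  storage.mode(M) <- "double"
  if (ncol(M) < 2) return(TRUE)
  c11 <- crossprod(M)            # rows with (1,1)
  c10 <- crossprod(M, 1 - M)     # rows with (1,0) as (p,q)
  conflict <- (c11 > 0) & (c10 > 0) & (t(c10) > 0)
  diag(conflict) <- FALSE
  !any(conflict)
}

#' Consistency between an extended completion and a predicted matrix
#'
#' Checks the defining identity of the extended-matrix reduction: for every
#' cell `c` and mutation `m`, `F[c, m]` equals the gain entry minus the sum
#' of the loss entries of `m` in `E`, and every such difference lies in
#' `{0, 1}`.
#'
#' @param E an [extended_matrix()].
#' @param I the observed [scs_matrix()] (shape reference).
#' @param F a complete binary matrix, cells x mutations.
#' @return `TRUE` iff the identity holds everywhere.
#' @export
check_dollo_completion <- function(E, I, F) {
  n_mut <- attr(E, "n_mutations")
  k <- attr(E, "k")
  if (!all(dim(F) == c(nrow(E), n_mut)) || !all(dim(I) == dim(F))) {
    stop("check_dollo_completion: inconsistent shapes", call. = FALSE)
  }
  d <- contract_extended(unclass(E), n_mut, k)
  all(d >= 0L & d <= 1L) && all(d == F)
}
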