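#' Single-cell mutation matrices
#'
#' An `scs_matrix` holds an incomplete binary cell-by-mutation observation
#' matrix: entry 1 means the mutation was called present in the cell, 0 means
#' called absent, and `NA` means no call could be made (insufficient
#' coverage). Internally it is an integer matrix with cells as rows and
#' mutations as columns, with labels kept as dimnames.
#'
#' @param entries matrix coercible to integer with values in `{0, 1, NA}`,
#'   cells as rows and mutations as columns.
#' @param cell_labels,mutation_labels optional character vectors; default to
#'   `cell1...` and `mut1...`.
#' @return an `scs_matrix` object.
#' @examples
#' scs_matrix(rbind(c(0, 1, NA), c(1, 0, 0)))
#' @export
scs_matrix <- function(entries, cell_labels = NULL, mutation_labels = NULL) {
  if (!is.matrix(entries)) entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  bad <- !is.na(entries) & !(entries %in% c(0L, 1L))
  if (any(bad)) {
    stop("scs_matrix entries must be 0, 1 or NA (missing); found ",
         entries[which(bad)[1]], call. = FALSE)
  }
  if (is.null(cell_labels)) cell_labels <- default_labels("cell", nrow(entries))
  if (is.null(mutation_labels)) mutation_labels <- default_labels("mut", ncol(entries))
  stopifnot(length(cell_labels) == nrow(entries),
            length(mutation_labels) == ncol(entries))
  dimnames(entries) <- list(cell_labels, mutation_labels)
  structure(entries, class = c("scs_matrix", "matrix", "array"))
}

default_labels <- function(prefix, n) {
  if (n == 0) character(0) else paste0(prefix, seq_len(n))
}

#' @export
print.scs_matrix <- function(x, ...) {
  cat(sprintf("<scs_matrix: %d cells x %d mutations, %d missing entries>\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(unclass(x), ...)
  invisible(x)
}

#' Number of cells / mutations of an `scs_matrix`
#' @param x an `scs_matrix`.
#' @return an integer count.
#' @export
n_cells <- function(x) nrow(x)

#' @rdname n_cells
#' @export
n_mutations <- function(x) ncol(x)

#' Read a single-cell mutation matrix
#'
#' Reads the plain-text ternary dialect used by most single-cell phylogeny
#' tools: whitespace-separated tokens from `{0, 1, 2}`, one matrix row per
#' line, where `2` marks a missing observation. The on-disk orientation is
#' never guessed from the shape; pass `orientation = "mutations"` when rows
#' of the file are mutations, and the returned matrix is transposed so that
#' it is always cells-by-mutations.
#'
#' @param path path to the matrix file.
#' @param orientation `"cells"` (rows of the file are cells, the default) or
#'   `"mutations"` (rows are mutations).
#' @param cell_labels,mutation_labels optional paths to sidecar label files
#'   (one label per line), or character vectors.
#' @return an [scs_matrix()].
#' @export
read_scs_matrix <- function(path, orientation = c("cells", "mutations"),
                            cell_labels = NULL, mutation_labels = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (length(toks) > 0) {
    w <- lengths(toks)
    if (any(w != w[1])) {
      bad <- which(w != w[1])[1]
      stop(sprintf("ragged matrix file '%s': line %d has %d tokens, expected %d",
                   path, bad, w[bad], w[1]), call. = FALSE)
    }
    flat <- unlist(toks)
    if (!all(flat %in% c("0", "1", "2"))) {
      bad <- setdiff(unique(flat), c("0", "1", "2"))[1]
      stop(sprintf("invalid token '%s' in matrix file '%s': entries must be 0, 1 or 2",
                   bad, path), call. = FALSE)
    }
    grid <- matrix(as.integer(flat), nrow = length(toks), byrow = TRUE)
  } else {
    grid <- matrix(integer(0), nrow = 0, ncol = 0)
  }
  grid[grid == 2L] <- NA_integer_
  if (orientation == "mutations") grid <- t(grid)
  read_labels <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) readLines(x) else x
  }
  scs_matrix(grid,
             cell_labels = read_labels(cell_labels),
             mutation_labels = read_labels(mutation_labels))
}

#' Write a single-cell mutation matrix
#'
#' Writes the ternary dialect read by [read_scs_matrix()] (cells as rows,
#' `2` for missing). Round-trips bit-exactly through [read_scs_matrix()].
#'
#' @param x an [scs_matrix()] (or plain 0/1/NA matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scs_matrix <- function(x, path) {
  m <- unclass(x)
  m[is.na(m)] <- 2L
  lines <- apply(m, 1, paste, collapse = " ")
  writeLines(as.character(lines), path)
  invisible(path)
}
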