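#' Build the maximum-likelihood Dollo(k) program
#'
#' Assembles the 0-1 program whose optimum is the maximum-likelihood
#' Dollo(k) explanation of an observed single-cell matrix. The variables
#' are: `E(c, p)` over the extended columns of [extended_columns()];
#' auxiliary `F(c, m) = E(c, m+) - sum_l E(c, ml-)` (binary, so a loss is
#' only possible on top of a gain); and pair-configuration indicators
#' `B(p, q, a, b)` for every unordered extended-column pair and
#' `(a, b)` in `{(0,1), (1,0), (1,1)}`, with `B(p,q,0,1) + B(p,q,1,0) +
#' B(p,q,1,1) <= 2` forbidding conflicting pairs. The objective is the
#' linearized log-likelihood `sum slope(c,m) F(c,m) + sum intercept(c,m)`
#' from [objective_coefficients()]. An optional cap bounds the number of
#' realized losses via per-loss-column usage indicators (a loss column
#' counts when any cell carries it).
#'
#' B variables are created per unordered pair with the roles of (0,1) and
#' (1,0) fixed by column order; the ordered-pair statement duplicates every
#' constraint without changing feasibility.
#'
#' @param I an [scs_matrix()].
#' @param rates an [error_rates()] object.
#' @param k Dollo parameter (losses allowed per mutation).
#' @param max_losses optional cap on the total number of realized losses.
#' @return a `dollo_ilp` model object; its `counts` element reports the
#'   variable and constraint census of the formulation.
#' @export
build_model <- function(I, rates, k = 1L, max_losses = NULL) {
  stopifnot(inherits(I, "scs_matrix"), k >= 0)
  n <- nrow(I); m <- ncol(I)
  cols <- extended_columns(m, k)
  D <- nrow(cols)
  n_pairs <- if (D >= 2) D * (D - 1) / 2 else 0
  n_loss_cols <- sum(cols$type == "loss")
  counts <- list(
    n_E = n * D,
    n_F = n * m,
    n_B = 3 * n_pairs,
    n_pairs = n_pairs,
    n_u = if (is.null(max_losses)) 0L else n_loss_cols,
    constraints = list(
      linking = n * m,                        # F = gain - sum losses
      pair_activation = 3 * n * n_pairs,      # B >= +/- differences, sums
      pair_cap = n_pairs,                     # sum of three B's <= 2
      loss_cap = if (is.null(max_losses)) 0L else n * n_loss_cols + 1L
    )
  )
  structure(
    list(I = I, rates = rates, k = as.integer(k),
         max_losses = if (is.null(max_losses)) NULL else as.integer(max_losses),
         coefficients = objective_coefficients(I, rates),
         columns = cols, counts = counts),
    class = "dollo_ilp"
  )
}

#' @export
print.dollo_ilp <- function(x, ...) {
  cat(sprintf(paste0(
    "<dollo_ilp: %d cells x %d mutations, k = %d%s>\n",
    "  variables: E %d, F %d, B %d (%d column pairs)%s\n",
    "  constraints: %d linking, %d pair activation, %d pair caps%s\n"),
    nrow(x$I), ncol(x$I), x$k,
    if (is.null(x$max_losses)) "" else paste0(", max losses ", x$max_losses),
    x$counts$n_E, x$counts$n_F, x$counts$n_B, x$counts$n_pairs,
    if (x$counts$n_u) paste0(", u ", x$counts$n_u) else "",
    x$counts$constraints$linking, x$counts$constraints$pair_activation,
    x$counts$constraints$pair_cap,
    if (x$counts$n_u) paste0(", ", x$counts$constraints$loss_cap, " loss cap") else ""))
  invisible(x)
}

#' Solve the Dollo(k) likelihood program
#'
#' Runs the package's exact branch-and-bound solver: depth-first search over
#' the per-(cell, mutation) extended-matrix assignments with incremental
#' propagation of the pairwise conflict constraints and an admissible
#' per-entry bound. The search is deterministic. With a timeout the best
#' feasible solution found so far (the incumbent) is returned with status
#' `"feasible-timeout"`; without one the search runs to proven optimality.
#'
#' @param model a [build_model()] object.
#' @param timeout wall-clock budget in seconds (`Inf` = solve to optimality).
#' @param seed accepted for interface stability; the solver is
#'   deterministic and does not consume randomness.
#' @param threads accepted for interface stability; the search is
#'   single-threaded.
#' @return a `dollo_ilp_solution` with elements `E_star` (an
#'   [extended_matrix()]), `F_star` (complete binary matrix), `objective`
#'   (log-likelihood), `status` (`"optimal"` or `"feasible-timeout"`) and
#'   `nodes` (search nodes explored).
#' @export
solve_ilp <- function(model, timeout = Inf, seed = NULL, threads = 1L) {
  stopifnot(inherits(model, "dollo_ilp"))
  co <- model$coefficients
  res <- bb_solve(co$slope, co$intercept, model$k,
                  if (is.null(model$max_losses)) -1L else model$max_losses,
                  as.numeric(timeout))
  if (is.null(res$options)) {
    stop("no feasible solution found within the timeout; increase the timeout",
         call. = FALSE)
  }
  sol <- solution_from_options(model, res$options, res$objective, res$status,
                               res$nodes)
  # contract checks: every returned completion must be conflict-free,
  # consistent with its predicted matrix, and have a self-consistent objective
  stopifnot(is_conflict_free(sol$E_star),
            check_dollo_completion(sol$E_star, model$I, sol$F_star))
  recomputed <- matrix_log_likelihood(model$I, sol$F_star, model$rates)
  stopifnot(abs(recomputed - sol$objective) <= 1e-6)
  sol
}

solution_from_options <- function(model, options, objective, status, nodes) {
  n <- nrow(model$I); m <- ncol(model$I); k <- model$k
  per <- k + 1L
  E <- matrix(0L, n, m * per)
  Fm <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    o <- options[, j]
    gcol <- (j - 1L) * per + 1L
    E[, gcol] <- as.integer(o >= 1L)
    if (k > 0) {
      for (l in seq_len(k)) E[, gcol + l] <- as.integer(o == 1L + l)
    }
    Fm[, j] <- as.integer(o == 1L)
  }
  structure(
    list(E_star = extended_matrix(E, m, k), F_star = Fm,
         objective = objective, status = status, nodes = nodes),
    class = "dollo_ilp_solution"
  )
}

#' @export
print.dollo_ilp_solution <- function(x, ...) {
  cat(sprintf("<dollo_ilp_solution: status %s, log-likelihood %.4f, %d losses, %.0f nodes>\n",
              x$status, x$objective, count_realized_losses(x$E_star), x$nodes))
  invisible(x)
}

# number of loss columns carried by at least one cell
count_realized_losses <- function(E) {
  cols <- attr(E, "columns")
  loss <- cols$index[cols$type == "loss"]
  if (!length(loss)) return(0L)
  sum(colSums(unclass(E)[, loss, drop = FALSE]) > 0)
}
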