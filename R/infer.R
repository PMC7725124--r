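#' End-to-end tumor phylogeny inference
#'
#' The full pipeline: solve the maximum-likelihood Dollo(k) program on the
#' observed matrix, extract the phylogeny from the conflict-free extended
#' completion, attach cells by maximum likelihood, and (optionally) refine
#' by SPR hill climbing. The hill-climbing score can only improve on the
#' solver's incumbent, never fall below it.
#'
#' @param input an [scs_matrix()] or a path readable by
#'   [read_scs_matrix()].
#' @param alpha,beta false-negative and false-positive rates (data
#'   properties; no defaults).
#' @param k Dollo parameter (default 1: each mutation lost at most once).
#' @param max_losses optional cap on the total number of realized losses.
#' @param timeout solver budget in seconds (`Inf` = prove optimality).
#' @param refine run the hill-climbing refinement (default `TRUE`).
#' @param neighbor_samples,max_iterations hill-climbing parameters.
#' @param seed integer seed for the refinement's neighbor sampling.
#' @param orientation passed to [read_scs_matrix()] when `input` is a path.
#' @return a `dollo_fit` object; see [tidy.dollo_fit()] and
#'   [glance.dollo_fit()] for tabular views.
#' @examples
#' sim <- simulate_scs(sim_config(n_subclones = 3, n_cells = 12,
#'                                n_mutations = 4, n_deletions = 1,
#'                                alpha = 0.05, beta = 1e-4, gamma = 0.05,
#'                                seed = 7))
#' fit <- run_infer(sim$observed, alpha = 0.05, beta = 1e-4, k = 1,
#'                  max_iterations = 5, seed = 7)
#' glance(fit)
#' @export
run_infer <- function(input, alpha, beta, k = 1L, max_losses = NULL,
                      timeout = Inf, refine = TRUE, neighbor_samples = 30L,
                      max_iterations = 100L, seed = NULL,
                      orientation = c("cells", "mutations")) {
  t0 <- proc.time()[["elapsed"]]
  I <- if (inherits(input, "scs_matrix")) input
       else read_scs_matrix(input, orientation = match.arg(orientation))
  rates <- error_rates(alpha, beta)
  model <- build_model(I, rates, k = k, max_losses = max_losses)
  sol <- solve_ilp(model, timeout = timeout, seed = seed)
  tree <- tree_from_extended_matrix(sol$E_star,
                                    mutation_labels = colnames(I))
  att <- best_attachment(tree, I, rates)
  ilp_objective <- sol$objective
  hc <- NULL
  if (refine) {
    hc <- hill_climb(tree, I, rates,
                     hillclimb_config(neighbor_samples, max_iterations, seed))
    # the attachment-based score of the extracted tree can exceed the
    # matrix objective (cells re-attach freely); keep whichever is better
    if (hc$log_likelihood >= att$log_likelihood) {
      tree <- hc$tree
      att <- hc[c("attachment", "log_likelihood")]
    }
  }
  structure(
    list(observed = I, rates = rates, k = as.integer(k),
         solution = sol, tree = tree, attachment = att$attachment,
         F_star = sol$F_star,
         ilp_objective = ilp_objective,
         hc_objective = if (refine) att$log_likelihood else NULL,
         log_likelihood = att$log_likelihood,
         status = sol$status,
         n_losses = sum(tree$type == "loss"),
         hc_trace = if (refine) hc$trace else NULL,
         config = list(alpha = alpha, beta = beta, k = k,
                       max_losses = max_losses, timeout = timeout,
                       refine = refine, neighbor_samples = neighbor_samples,
                       max_iterations = max_iterations, seed = seed),
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "dollo_fit"
  )
}

#' @export
print.dollo_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<dollo_fit: %d cells x %d mutations, k = %d>\n",
    "  solver: %s, log-likelihood %.4f\n"),
    nrow(x$observed), ncol(x$observed), x$k, x$status, x$ilp_objective))
  if (!is.null(x$hc_objective)) {
    cat(sprintf("  after hill climbing: %.4f\n", x$hc_objective))
  }
  cat(sprintf("  tree: %d nodes, %d losses\n", nrow(x$tree), x$n_losses))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the inferred tree
#'
#' One row per tree node, with human-readable labels and the number of
#' attached cells.
#'
#' @param x a `dollo_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.dollo_fit <- function(x, ...) {
  labs <- attr(x$tree, "mutation_labels")
  counts <- table(x$attachment$node)
  dplyr::mutate(
    tibble::as_tibble(x$tree),
    label = dplyr::case_when(
      type == "root" ~ "germline",
      type == "gain" ~ labs[mutation],
      TRUE ~ paste0(labs[mutation], "-")
    ),
    n_cells = as.integer(ifelse(is.na(match(id, names(counts))), 0L,
                                counts[as.character(id)]))
  )
}

#' One-row summary of a fit
#'
#' @param x a `dollo_fit`.
#' @param ... unused.
#' @return a one-row tibble with objectives, solver status, loss count and
#'   timing.
#' @export
glance.dollo_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$observed),
    n_mutations = ncol(x$observed),
    k = x$k,
    ilp_objective = x$ilp_objective,
    hc_objective = if (is.null(x$hc_objective)) NA_real_ else x$hc_objective,
    log_likelihood = x$log_likelihood,
    status = x$status,
    n_losses = x$n_losses,
    wall_time = x$wall_time
  )
}

#' Machine-readable run report
#'
#' @param x a `dollo_fit`.
#' @param path optional path; when given, the report is written as JSON.
#' @return the report list, invisibly when writing.
#' @export
run_report <- function(x, path = NULL) {
  rep <- list(
    status = x$status,
    ilp_objective = x$ilp_objective,
    hc_objective = x$hc_objective,
    n_losses = x$n_losses,
    wall_time = x$wall_time,
    config = x$config[!vapply(x$config, is.null, logical(1))]
  )
  rep <- rep[!vapply(rep, is.null, logical(1))]
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

tree_layout <- function(tree) {
  kids <- children_of(tree)
  row_of <- integer(max(tree$id)); row_of[tree$id] <- seq_len(nrow(tree))
  xs <- numeric(nrow(tree)); ys <- numeric(nrow(tree))
  leaf_x <- 0
  assign_xy <- function(v, depth) {
    ch <- kids[[v]]
    ys[row_of[v]] <<- -depth
    if (is.null(ch) || !length(ch)) {
      leaf_x <<- leaf_x + 1
      xs[row_of[v]] <<- leaf_x
    } else {
      for (w in sort(ch)) assign_xy(w, depth + 1)
      xs[row_of[v]] <<- mean(xs[row_of[sort(ch)]])
    }
  }
  assign_xy(tree_root_id(tree), 0)
  tibble::tibble(id = tree$id, x = xs, y = ys, type = tree$type)
}

#' Plot an inferred phylogeny
#'
#' Simple layered tree drawing: gains as labeled boxes, losses in red, edge
#' segments between parent and child.
#'
#' @param object a `dollo_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dollo_fit <- function(object, ...) {
  plot_tree(object$tree, attachment = object$attachment)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.dollo_fit
#' @param tree a [phylo_tree()].
#' @param attachment optional [cell_attachment()] (adds cell counts).
#' @export
plot_tree <- function(tree, attachment = NULL) {
  lay <- tree_layout(tree)
  labs <- attr(tree, "mutation_labels")
  row_of <- match(tree$id, tree$id)
  lay$label <- vapply(seq_len(nrow(tree)), function(r) node_display_label(tree, r),
                      character(1))
  if (!is.null(attachment)) {
    counts <- table(attachment$node)
    extra <- counts[as.character(lay$id)]
    lay$label <- ifelse(is.na(extra), lay$label,
                        paste0(lay$label, " (", extra, ")"))
  }
  seg <- dplyr::inner_join(
    dplyr::transmute(tibble::as_tibble(tree), id = id, parent = parent),
    dplyr::rename(lay[, c("id", "x", "y")], px = x, py = y),
    by = c("parent" = "id"))
  seg <- dplyr::inner_join(seg, lay[, c("id", "x", "y")], by = "id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = .data$py,
                                       xend = .data$x, yend = .data$y),
                          color = "grey50") +
    ggplot2::geom_label(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label,
                                     color = .data$type == "loss"),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::theme_void()
}

#' Plot a hill-climbing trace
#'
#' @param x a `dollo_fit` fitted with `refine = TRUE`.
#' @return a ggplot object showing the accepted score per iteration.
#' @export
plot_hc_trace <- function(x) {
  stopifnot(!is.null(x$hc_trace))
  ggplot2::ggplot(x$hc_trace,
                  ggplot2::aes(x = .data$iteration, y = .data$current)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
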