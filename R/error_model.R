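#' Error rates of the single-cell observation model
#'
#' The observation model assumes independent per-entry errors: a truly
#' present mutation is observed absent (allelic dropout) with probability
#' `alpha` (false-negative rate) and a truly absent mutation is observed
#' present with probability `beta` (false-positive rate):
#'
#' \deqn{P(I=1 \mid E=1) = 1-\alpha, \quad P(I=0 \mid E=1) = \alpha,}
#' \deqn{P(I=1 \mid E=0) = \beta,   \quad P(I=0 \mid E=0) = 1-\beta.}
#'
#' Missing observations carry no information and contribute nothing to the
#' likelihood. Rates are clamped to `[1e-9, 1 - 1e-9]` so that noise-free
#' configurations remain usable (no `log(0)`).
#'
#' Non-uniform rates: `alpha_matrix`/`beta_matrix` optionally override the
#' global rates per (cell, mutation) entry; the formulation is unchanged
#' because the rates enter only as constants.
#'
#' @param alpha false-negative rate in (0, 1).
#' @param beta false-positive rate in (0, 1).
#' @param alpha_matrix,beta_matrix optional numeric matrices of per-entry
#'   rates (cells x mutations); `NA` entries fall back to the global rate.
#' @return an `error_rates` object.
#' @examples
#' error_rates(0.1, 1e-4)
#' @export
error_rates <- function(alpha, beta, alpha_matrix = NULL, beta_matrix = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.numeric(beta), length(beta) == 1)
  clamp <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
  structure(
    list(alpha = clamp(alpha), beta = clamp(beta),
         alpha_matrix = if (!is.null(alpha_matrix)) clamp(alpha_matrix),
         beta_matrix = if (!is.null(beta_matrix)) clamp(beta_matrix)),
    class = "error_rates"
  )
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("<error_rates: alpha (FN) = %g, beta (FP) = %g%s>\n",
              x$alpha, x$beta,
              if (!is.null(x$alpha_matrix) || !is.null(x$beta_matrix))
                ", with per-entry overrides" else ""))
  invisible(x)
}

# Per-entry (alpha, beta) grids for an n x m problem, applying overrides.
rate_grids <- function(rates, n, m) {
  a <- matrix(rates$alpha, n, m)
  b <- matrix(rates$beta, n, m)
  if (!is.null(rates$alpha_matrix)) {
    o <- rates$alpha_matrix
    stopifnot(all(dim(o) == c(n, m)))
    a[!is.na(o)] <- o[!is.na(o)]
  }
  if (!is.null(rates$beta_matrix)) {
    o <- rates$beta_matrix
    stopifnot(all(dim(o) == c(n, m)))
    b[!is.na(o)] <- o[!is.na(o)]
  }
  list(alpha = a, beta = b)
}

#' Log-probability of one observed entry
#'
#' Natural log of \eqn{P(I[c,m] = \mathrm{observed} \mid E[c,m] =
#' \mathrm{predicted})}. A missing observation returns exactly 0: unknown
#' entries do not factor into the objective.
#'
#' @param observed observed entry: 0, 1 or `NA` (missing).
#' @param predicted predicted entry: 0 or 1.
#' @param rates an [error_rates()] object.
#' @param cell,mutation 1-based indices, used only to look up per-entry rate
#'   overrides.
#' @return a log-probability (scalar).
#' @export
entry_log_prob <- function(observed, predicted, rates, cell = 1L, mutation = 1L) {
  stopifnot(predicted %in% c(0L, 1L))
  if (is.na(observed)) return(0)
  stopifnot(observed %in% c(0L, 1L))
  a <- rates$alpha
  b <- rates$beta
  if (!is.null(rates$alpha_matrix) && !is.na(rates$alpha_matrix[cell, mutation]))
    a <- rates$alpha_matrix[cell, mutation]
  if (!is.null(rates$beta_matrix) && !is.na(rates$beta_matrix[cell, mutation]))
    b <- rates$beta_matrix[cell, mutation]
  if (predicted == 1L) {
    if (observed == 1L) log(1 - a) else log(a)
  } else {
    if (observed == 1L) log(b) else log(1 - b)
  }
}

#' Per-entry linear objective coefficients
#'
#' The log-likelihood of a predicted entry is linear in the predicted value
#' `F`: for an observed 1 it equals \eqn{\log\beta + F\,\log((1-\alpha)/\beta)},
#' for an observed 0 it equals \eqn{\log(1-\beta) + F\,\log(\alpha/(1-\beta))},
#' and for a missing observation both coefficients are 0. These (slope,
#' intercept) pairs linearize the likelihood objective of the search.
#'
#' @param I an [scs_matrix()].
#' @param rates an [error_rates()] object.
#' @return a list with numeric matrices `slope` and `intercept`, both
#'   cells x mutations, such that `slope * F + intercept` is the entry
#'   log-likelihood for `F` in `{0, 1}`.
#' @export
objective_coefficients <- function(I, rates) {
  n <- nrow(I); m <- ncol(I)
  g <- rate_grids(rates, n, m)
  slope <- matrix(0, n, m)
  intercept <- matrix(0, n, m)
  one <- !is.na(I) & I == 1L
  zero <- !is.na(I) & I == 0L
  slope[one] <- log((1 - g$alpha[one]) / g$beta[one])
  intercept[one] <- log(g$beta[one])
  slope[zero] <- log(g$alpha[zero] / (1 - g$beta[zero]))
  intercept[zero] <- log(1 - g$beta[zero])
  list(slope = slope, intercept = intercept)
}

#' Log-likelihood of a complete predicted matrix
#'
#' Sum over all known entries of the observation log-probabilities; the log
#' of the product likelihood restricted to known entries.
#'
#' @param I an [scs_matrix()] (observed, possibly incomplete).
#' @param F a complete binary matrix of the same shape (predicted genotypes).
#' @param rates an [error_rates()] object.
#' @return the total log-likelihood (scalar).
#' @export
matrix_log_likelihood <- function(I, F, rates) {
  if (!all(dim(I) == dim(F))) {
    stop(sprintf("shape mismatch: observed is %dx%d, predicted is %dx%d",
                 nrow(I), ncol(I), nrow(F), ncol(F)), call. = FALSE)
  }
  co <- objective_coefficients(I, rates)
  sum(co$slope * F) + sum(co$intercept)
}
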