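#' Numerical singularity of a matrix
#'
#' A matrix counts as numerically singular when its 2-norm condition number
#' exceeds the inverse of the floating-point precision (machine spacing at
#' 1), the same criterion used to flag ill-conditioned trust-region
#' subproblems in the per-iteration trace.
#'
#' @param B square matrix.
#' @return logical flag.
#' @export
is_numerically_singular <- function(B) {
  sv <- svd(B, nu = 0, nv = 0)$d
  if (!length(sv) || max(sv) == 0) return(TRUE)
  if (min(sv) == 0) return(TRUE)
  (max(sv) / min(sv)) > 1 / .Machine$double.eps
}

#' Negative eigenvalue beyond numerical noise
#'
#' `TRUE` when `lambda_min(B) < -eps * abs(lambda_max(B))` with `eps` the
#' machine spacing at 1, i.e. the smallest eigenvalue is negative by more
#' than the noise floor of the eigensolver.
#'
#' @param B symmetric matrix.
#' @return logical flag.
#' @export
has_negative_eigenvalue <- function(B) {
  lam <- eigen(symmetrize(as.matrix(B)), symmetric = TRUE,
               only.values = TRUE)$values
  min(lam) < -.Machine$double.eps * max(abs(lam))
}

#' Multistart performance metrics
#'
#' Success count, convergence rate and performance of a multistart study:
#' `gamma` counts runs whose final objective lies within `tau` of the lowest
#' final value, `nu = 1 / n_grad_total` is the convergence rate (gradient
#' evaluations equal iterations for this optimizer), and
#' `phi = gamma / n_grad_total = gamma * nu` is the performance. Non-finite
#' final values (failed runs) are excluded from the minimum and counted as
#' unsuccessful, but their gradient evaluations stay in `n_grad_total`.
#'
#' @param final_values numeric vector of per-run final objective values.
#' @param n_grad_total total gradient evaluations across all runs.
#' @param tau success threshold on the distance to the best final value
#'   (default 2, the non-rejection limit under the Akaike information
#'   criterion for the one-half-scaled negative log-likelihood).
#' @return list with `gamma`, `nu`, `phi`, `tau`, `n_grad_total`.
#' @export
compute_metrics <- function(final_values, n_grad_total, tau = 2) {
  if (!length(final_values)) stop("at least one finished run is required")
  finite <- final_values[is.finite(final_values)]
  gamma <- if (length(finite)) sum(finite - min(finite) < tau) else 0L
  gamma <- as.integer(gamma)
  nu <- 1 / n_grad_total
  list(gamma = gamma, nu = nu, phi = gamma * nu,
       tau = tau, n_grad_total = n_grad_total)
}

#' Per-run trace statistics
#'
#' Fractions of iterations with notable numerical events, computed from the
#' trace of a [tr_minimize()] result: numerically singular transformed
#' Hessian, no trust-region-radius update, no Hessian-approximation update,
#' evaluation (integration) failures, boundary-constrained iterations,
#' constrained-Cauchy steps, and negative eigenvalues of the approximation.
#'
#' @param result a `"tr_result"` (or its `trace` data frame).
#' @return named list of fractions, each in `[0, 1]`.
#' @export
trace_statistics <- function(result) {
  tr <- if (is.data.frame(result)) result else result$trace
  if (!nrow(tr)) stop("trace is empty")
  m <- nrow(tr)
  list(
    frac_singular_hessian = sum(tr$singular_hessian) / m,
    frac_no_radius_update = sum(!tr$radius_updated) / m,
    frac_no_hessian_update = sum(!tr$hessian_updated) / m,
    frac_eval_failed = sum(tr$eval_failed) / m,
    frac_boundary_constrained = sum(tr$boundary_constrained) / m,
    frac_cauchy_steps = sum(tr$step_kind == "cauchy") / m,
    frac_negative_eigenvalue = sum(tr$negative_eigenvalue) / m)
}

#' Overlap score of successful start points
#'
#' Jaccard index of the two sets of start-point indices that yielded
#' successful runs under two optimizer settings; two empty sets score 0 by
#' convention.
#'
#' @param a,b vectors of start-point indices.
#' @return scalar in `[0, 1]`.
#' @export
startpoint_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  uni <- union(a, b)
  if (!length(uni)) return(0)
  length(intersect(a, b)) / length(uni)
}
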