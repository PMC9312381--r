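#' Coleman-Li affine scaling vector
#'
#' Computes the distance-to-bound scaling vector `v` and the diagonal `dv`
#' of the Jacobian of `|v|` used by the interior-reflective method. The four
#' branches, per coordinate `i`:
#'
#' * `g_i < 0` and `u_i` finite: `v_i = theta_i - u_i`, `dv_i = -1`
#' * `g_i >= 0` and `l_i` finite: `v_i = theta_i - l_i`, `dv_i = +1`
#' * `g_i < 0` and `u_i = Inf`: `v_i = -1`, `dv_i = 0`
#' * `g_i >= 0` and `l_i = -Inf`: `v_i = 1`, `dv_i = 0`
#'
#' `dv` is the derivative of `|v|`, so the model augmentation
#' `diag(g) %*% dv` is elementwise nonnegative for every admissible state.
#'
#' @param theta current iterate, strictly inside the domain.
#' @param g gradient at `theta`.
#' @param domain a [search_domain()].
#' @return list with `v` and `dv` (numeric vectors).
#' @export
scaling_vector <- function(theta, g, domain) {
  if (!is_interior(theta, domain))
    stop("theta must be strictly inside the search domain (interior method)")
  l <- domain$lower
  u <- domain$upper
  v <- numeric(length(theta))
  dv <- numeric(length(theta))
  neg <- g < 0
  b1 <- neg & is.finite(u)
  b2 <- !neg & is.finite(l)
  b3 <- neg & !is.finite(u)
  b4 <- !neg & !is.finite(l)
  v[b1] <- theta[b1] - u[b1]; dv[b1] <- -1
  v[b2] <- theta[b2] - l[b2]; dv[b2] <- 1
  v[b3] <- -1
  v[b4] <- 1
  list(v = v, dv = dv)
}

#' Transformed trust-region model near bounds
#'
#' Builds the affine-scaled model quantities: `D = diag(|v|^(1/2))`,
#' `B_hat = D B D + diag(g * dv)`, `g_hat = D g`. The diagonal augmentation
#' `g * dv` is elementwise nonnegative, so the transformation can only
#' regularize the subproblem. Also returns `B_eff`, the same model expressed
#' in original coordinates (`B_eff = B + diag(g * dv / |v|)`), used to score
#' stepback candidates: for `p = D p_hat`,
#' `quad_model_value(g, B_eff, p) == quad_model_value(g_hat, B_hat, p_hat)`.
#'
#' @param B model Hessian (original coordinates).
#' @param g gradient.
#' @param v,dv from [scaling_vector()].
#' @return list with `B_hat`, `g_hat`, `D` (vector of diagonal entries),
#'   `B_eff`, `aug` (the augmentation diagonal `g * dv`).
#' @export
transform_model <- function(B, g, v, dv) {
  d <- sqrt(abs(v))
  aug <- g * dv
  B_hat <- symmetrize(d * t(d * B)) + diag(aug, length(g))
  B_eff <- symmetrize(B + diag(aug / abs(v), length(g)))
  list(B_hat = B_hat, g_hat = d * g, D = d, B_eff = B_eff, aug = aug)
}

# Distance along direction dir from x to the first boundary crossing;
# returns the distance and the coordinate index (0 if never).
first_crossing <- function(x, dir, domain) {
  t_best <- Inf
  idx <- 0L
  for (i in seq_along(x)) {
    ti <- Inf
    if (dir[i] > 0 && is.finite(domain$upper[i]))
      ti <- (domain$upper[i] - x[i]) / dir[i]
    else if (dir[i] < 0 && is.finite(domain$lower[i]))
      ti <- (domain$lower[i] - x[i]) / dir[i]
    if (ti < t_best) { t_best <- ti; idx <- i }
  }
  list(t = t_best, index = idx)
}

#' Reflected step at the box boundary
#'
#' Follows the piecewise-linear path obtained by reflecting the proposed
#' step `p` at every bound it crosses, up to a total arc length of
#' `norm(p)`. On each linear segment the quadratic model (gradient `g`,
#' Hessian `B` in original coordinates) is minimized analytically; the walk
#' stops at the first segment whose minimizer is interior to the segment
#' (the first local minimum along the path). `max_reflections = 1`
#' reproduces the single-reflection variant (at most two segments are
#' examined). The returned candidate is pulled strictly inside the domain.
#'
#' @param p proposed step (original coordinates), nonzero.
#' @param theta current iterate, strictly interior.
#' @param domain a [search_domain()].
#' @param g,B gradient and model Hessian in original coordinates (use
#'   `B_eff` from [transform_model()] for the scaled model).
#' @param max_reflections maximum number of boundary reflections
#'   (`Inf` = reflect until the first local minimum; a safety cap of
#'   `100 * length(p)` reflections guards against degenerate cycling).
#' @return step candidate with `kind = "reflected"`.
#' @export
reflect_step <- function(p, theta, domain, g, B, max_reflections = Inf) {
  L <- sqrt(sum(p^2))
  if (L == 0) stop("proposed step must be nonzero")
  dir <- p / L
  x <- theta
  traveled <- 0
  n_ref <- 0L
  cap <- min(max_reflections, 100 * length(p))
  best_val <- Inf
  best_x <- theta + p
  repeat {
    cr <- first_crossing(x, dir, domain)
    seg_len <- min(cr$t, L - traveled)
    p0 <- x - theta
    a <- 0.5 * sum(dir * drop(B %*% dir))
    b <- sum(dir * (g + drop(B %*% p0)))
    # candidate positions on this segment: interior stationary point or end
    t_int <- if (a > 0) -b / (2 * a) else NA_real_
    has_interior_min <- is.finite(t_int) && t_int > 0 && t_int < seg_len
    t_eval <- if (has_interior_min) t_int else seg_len
    val <- quad_model_value(g, B, p0 + t_eval * dir)
    if (val < best_val) {
      best_val <- val
      best_x <- x + t_eval * dir
    }
    if (has_interior_min) break            # first local minimum along path
    traveled <- traveled + seg_len
    if (traveled >= L * (1 - 1e-14)) break # path length exhausted
    if (n_ref >= cap) break
    # reflect the crossing coordinate
    x <- x + seg_len * dir
    i <- cr$index
    x[i] <- if (dir[i] > 0) domain$upper[i] else domain$lower[i]
    dir[i] <- -dir[i]
    n_ref <- n_ref + 1L
  }
  x_new <- force_interior(best_x, domain)
  step_candidate(x_new - theta, "reflected", g, B)
}

#' Step truncated at the box boundary
#'
#' Scales the proposal `p` by the largest factor in `[0, 1]` that keeps
#' `theta + alpha * p` inside the domain, then backs off strictly interior.
#'
#' @inheritParams reflect_step
#' @return step candidate with `kind = "truncated"`.
#' @export
truncate_step <- function(p, theta, domain, g, B) {
  alpha <- 1
  for (i in seq_along(p)) {
    if (p[i] > 0 && is.finite(domain$upper[i]))
      alpha <- min(alpha, (domain$upper[i] - theta[i]) / p[i])
    else if (p[i] < 0 && is.finite(domain$lower[i]))
      alpha <- min(alpha, (domain$lower[i] - theta[i]) / p[i])
  }
  alpha <- max(alpha, 0)
  x_new <- force_interior(theta + alpha * p, domain)
  step_candidate(x_new - theta, "truncated", g, B)
}

#' Constrained Cauchy step
#'
#' Minimizes the scaled quadratic model along the scaled steepest-descent
#' direction, truncated at both the trust region (in scaled coordinates) and
#' the box boundary. With positive curvature along the direction the exact
#' 1-D minimizer is used; otherwise the step extends to the nearest of the
#' two boundaries. The candidate is backed off strictly interior.
#'
#' @param g,B gradient and model Hessian in original coordinates (`B_eff`).
#' @param theta current iterate.
#' @param domain a [search_domain()].
#' @param delta trust-region radius (scaled coordinates).
#' @param D diagonal of the affine scaling matrix (from [transform_model()]).
#' @return step candidate with `kind = "cauchy"`.
#' @export
constrained_cauchy <- function(g, B, theta, domain, delta, D) {
  g_hat <- D * g
  ng <- sqrt(sum(g_hat^2))
  if (ng == 0) stop("gradient must be nonzero for the Cauchy step")
  dir_hat <- -g_hat / ng                     # unit, scaled coordinates
  dir <- D * dir_hat                         # original coordinates
  # box limit on t (p(t) = t * dir)
  t_box <- Inf
  for (i in seq_along(dir)) {
    if (dir[i] > 0 && is.finite(domain$upper[i]))
      t_box <- min(t_box, (domain$upper[i] - theta[i]) / dir[i])
    else if (dir[i] < 0 && is.finite(domain$lower[i]))
      t_box <- min(t_box, (domain$lower[i] - theta[i]) / dir[i])
  }
  t_max <- min(delta, t_box)
  kappa <- sum(dir * drop(B %*% dir))        # curvature along the line
  slope <- sum(g * dir)                      # = -||g_hat||
  t_star <- if (kappa > 0) min(-slope / kappa, t_max) else t_max
  t_star <- max(t_star, 0)
  x_new <- force_interior(theta + t_star * dir, domain)
  step_candidate(x_new - theta, "cauchy", g, B)
}

#' Select the best stepback candidate
#'
#' Returns the candidate with the lowest quadratic-model value. Ties are
#' broken by preferring the larger step norm, then by the fixed kind order
#' reflected, truncated, cauchy.
#'
#' @param candidates nonempty list of step candidates.
#' @return the selected candidate.
#' @export
select_step <- function(candidates) {
  if (!length(candidates)) stop("candidate list must be nonempty")
  kind_rank <- c(reflected = 1, truncated = 2, cauchy = 3)
  vals <- vapply(candidates, `[[`, numeric(1), "model_value")
  norms <- vapply(candidates, `[[`, numeric(1), "norm")
  ranks <- vapply(candidates, function(cn)
    kind_rank[[cn$kind]] %||% 4, numeric(1))
  ord <- order(vals, -norms, ranks)
  candidates[[ord[1]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
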