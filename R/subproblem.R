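#' Quadratic model decrease value
#'
#' Value of the local quadratic model relative to its expansion point,
#' \eqn{q(p) = g^T p + \frac{1}{2} p^T B p} (the constant `f` is omitted,
#' so `q(0) = 0` and the predicted decrease of a step is `-q(p)`).
#'
#' @param g gradient vector.
#' @param B symmetric model Hessian.
#' @param p step vector.
#' @return scalar model value.
#' @export
quad_model_value <- function(g, B, p) {
  sum(g * p) + 0.5 * sum(p * drop(B %*% p))
}

step_candidate <- function(p, kind, g, B) {
  list(p = p, kind = kind, model_value = quad_model_value(g, B, p),
       norm = sqrt(sum(p^2)))
}

check_symmetric <- function(B) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B) ||
      max(abs(B - t(B))) > 1e-8 * max(1, max(abs(B))))
    stop("model Hessian must be symmetric")
  symmetrize(B)
}

#' Exact solution of the trust-region subproblem (full space)
#'
#' Computes the global minimizer of the quadratic model
#' \eqn{q(p) = g^T p + \frac{1}{2} p^T B p} over the ball
#' \eqn{\|p\| \le \Delta} via eigendecomposition of `B` and safeguarded
#' root-finding on the secular equation for the Lagrange multiplier,
#' including the hard case (gradient orthogonal to the most-negative
#' eigenspace), following the classical exact approach. Valid for
#' indefinite `B`.
#'
#' @param g gradient vector.
#' @param B symmetric matrix (may be indefinite).
#' @param delta trust-region radius, positive.
#' @param tol tolerance on the boundary equation `abs(norm(p) - delta)`.
#' @return a step candidate: list with `p`, `kind = "exactND"`,
#'   `model_value`, `norm`.
#' @export
solve_tr_nd <- function(g, B, delta, tol = 1e-10) {
  stopifnot(delta > 0)
  B <- check_symmetric(B)
  n <- length(g)
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values
  Q <- e$vectors
  w <- drop(crossprod(Q, g))
  lam_min <- min(lam)

  p_of <- function(mu) {
    d <- lam + mu
    coef <- ifelse(abs(d) > 0, -w / d, 0)
    coef[abs(d) <= .Machine$double.xmin] <- 0
    drop(Q %*% coef)
  }
  norm_of <- function(mu) {
    d <- lam + mu
    bad <- abs(d) < 1e-300
    if (any(bad & abs(w) > 0)) return(Inf)
    sqrt(sum((w[!bad] / d[!bad])^2))
  }

  # interior Newton point for positive definite B
  if (lam_min > 0) {
    p <- drop(Q %*% (-w / lam))
    if (sqrt(sum(p^2)) <= delta)
      return(step_candidate(p, "exactND", g, B))
  }

  mu_lo <- max(0, -lam_min)
  shift <- 1e-12 * max(1, abs(lam_min))
  mu0 <- mu_lo + shift
  if (norm_of(mu0) >= delta) {
    # boundary solution: root of ||p(mu)|| = delta on (mu0, mu_hi]
    mu_hi <- mu_lo + sqrt(sum(w^2)) / delta + shift
    while (norm_of(mu_hi) > delta) mu_hi <- mu_lo + 2 * (mu_hi - mu_lo)
    f <- function(mu) 1 / delta - 1 / norm_of(mu)
    root <- stats::uniroot(f, c(mu0, mu_hi), tol = 1e-15 * max(1, mu_hi),
                           maxiter = 200)
    p <- p_of(root$root)
    np <- sqrt(sum(p^2))
    if (abs(np - delta) > tol && np > 0) p <- p * (delta / np)
    return(step_candidate(p, "exactND", g, B))
  }

  if (mu_lo == 0) {
    # positive semi-definite, consistent: minimum-norm Newton point
    ok <- lam > 1e-12 * max(abs(lam), 1)
    coef <- rep(0, n)
    coef[ok] <- -w[ok] / lam[ok]
    return(step_candidate(drop(Q %*% coef), "exactND", g, B))
  }

  # hard case: pseudo-solution at mu = -lam_min plus a component along the
  # most-negative eigenvector to reach the boundary
  deg <- lam - lam_min <= 1e-10 * max(abs(lam), 1)
  coef <- rep(0, n)
  coef[!deg] <- -w[!deg] / (lam[!deg] + mu_lo)
  p_base <- drop(Q %*% coef)
  nb2 <- sum(p_base^2)
  t_len <- sqrt(max(delta^2 - nb2, 0))
  v <- Q[, which.min(lam)]
  if (sum(g * v) > 0) v <- -v
  step_candidate(p_base + t_len * v, "negative-curvature", g, B)
}

#' Minimum-norm Newton direction
#'
#' Solves `B d = -g` in the least-squares, minimum-norm sense via the
#' Moore–Penrose pseudoinverse (SVD with a relative singular-value cutoff),
#' so the direction is defined for singular `B` as well.
#'
#' @param B symmetric matrix.
#' @param g gradient vector.
#' @return direction vector `d`.
#' @export
newton_direction <- function(B, g) {
  B <- check_symmetric(B)
  sv <- svd(B)
  pos <- sv$d > max(sv$d) * length(g) * .Machine$double.eps
  if (!any(pos)) return(rep(0, length(g)))
  coef <- crossprod(sv$u[, pos, drop = FALSE], -g) / sv$d[pos]
  drop(sv$v[, pos, drop = FALSE] %*% coef)
}

#' Direction of strongest negative curvature
#'
#' Returns the unit eigenvector of the most negative eigenvalue of `B` when
#' that eigenvalue is negative beyond numerical noise
#' (`lambda_min < -eps * abs(lambda_max)` with `eps` the machine spacing at
#' 1), signed so that `g' v <= 0`; otherwise `NULL`.
#'
#' @param B symmetric matrix.
#' @param g gradient used only to pick the descent sign (optional).
#' @return unit vector or `NULL`.
#' @export
negative_curvature_direction <- function(B, g = NULL) {
  B <- check_symmetric(B)
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values
  if (!(min(lam) < -.Machine$double.eps * max(abs(lam)))) return(NULL)
  v <- e$vectors[, which.min(lam)]
  if (!is.null(g) && sum(g * v) > 0) v <- -v
  v
}

#' Two-dimensional-subspace solution of the trust-region subproblem
#'
#' Solves the subproblem restricted to the plane spanned by the gradient and
#' the (pseudoinverse) Newton direction; when `B` has a negative eigenvalue
#' beyond numerical noise the Newton direction is replaced by the direction
#' of strongest negative curvature. The restricted 2-by-2 problem is solved
#' exactly with [solve_tr_nd()]. Degenerate (parallel) bases collapse to an
#' exact line search.
#'
#' @inheritParams solve_tr_nd
#' @return a step candidate with `kind = "subspace2d"`.
#' @export
solve_tr_2d <- function(g, B, delta) {
  stopifnot(delta > 0)
  B <- check_symmetric(B)
  n <- length(g)
  gn <- sqrt(sum(g^2))
  if (gn == 0)
    return(step_candidate(rep(0, n), "subspace2d", g, B))
  b1 <- g / gn
  v <- negative_curvature_direction(B, g)
  if (is.null(v)) v <- newton_direction(B, g)
  v_perp <- v - sum(v * b1) * b1
  nv <- sqrt(sum(v_perp^2))
  if (nv < 1e-12 * max(1, sqrt(sum(v^2)))) {
    # basis degenerates to the gradient line: exact 1-D trust-region solve
    a <- 0.5 * sum(b1 * drop(B %*% b1))
    b <- sum(g * b1)
    cand_t <- c(-delta, delta)
    if (a > 0) {
      t_star <- -b / (2 * a)
      if (abs(t_star) < delta) cand_t <- c(cand_t, t_star)
    }
    vals <- a * cand_t^2 + b * cand_t
    t_best <- cand_t[which.min(vals)]
    return(step_candidate(t_best * b1, "subspace2d", g, B))
  }
  S <- cbind(b1, v_perp / nv)
  B2 <- crossprod(S, B %*% S)
  g2 <- drop(crossprod(S, g))
  sub <- solve_tr_nd(g2, symmetrize(B2), delta)
  step_candidate(drop(S %*% sub$p), "subspace2d", g, B)
}
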