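# Run code under a fixed RNG seed without disturbing the caller's RNG
# stream; keeps fixtures bit-reproducible.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_orthonormal <- function(nrow, ncol) {
  qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))[, seq_len(ncol),
                                                          drop = FALSE]
}

#' Synthetic nonlinear least-squares problem
#'
#' Generates a smooth nonlinear least-squares problem with a constructed
#' optimum: residuals are an affine map composed with a monotone
#' coordinate-wise sine warp plus a quadratic residual-curvature term,
#' \deqn{r(\theta) = A\,(w(\theta) - w(\theta^*)) + c + q(\theta), \quad
#'       w_i(t) = t + \alpha \sin(t - \theta^*_i),}
#' with `c` in the null space of `t(A)` so that the gradient of
#' `f = 0.5 * ||r||^2` vanishes at `theta_true` while `||r(theta_true)||`
#' equals the requested residual norm (the non-zero-residual regime). The
#' eigenvalues of the Gauss-Newton matrix at the optimum are log-spaced over
#' `spectrum_decades` decades, emulating the broad ("sloppy") spectra of
#' biochemical-model likelihoods.
#'
#' The curvature term `q_i(theta) = 0.5 * (c_i / ||c||^2) * curvature *
#' d' S d` (with `d = theta - theta_true` and `S` a random positive
#' semi-definite matrix of unit spectral norm) vanishes to first order at
#' the optimum, so it changes neither the residual norm, the gradient, nor
#' the GN matrix there — but it makes the true Hessian at the optimum
#' `GN + curvature * S`, the regime in which GN genuinely misses the
#' residual curvature. With `residual_norm_at_opt = 0` the term drops out
#' and GN is the exact Hessian at `theta_true`.
#'
#' @param n_par number of parameters.
#' @param n_res number of residuals (`>= n_par`; strictly greater when
#'   `residual_norm_at_opt > 0`).
#' @param residual_norm_at_opt residual norm at the constructed optimum.
#' @param spectrum_decades decades spanned by the GN eigenvalues at the
#'   optimum (0 = perfectly conditioned).
#' @param domain a [search_domain()] with finite bounds (default
#'   `[-3, 3]^n_par`).
#' @param seed integer seed; identical seeds give bit-identical problems.
#' @param alpha warp amplitude in `[0, 1)`; controls nonlinearity while
#'   keeping the warp monotone (default 0.3).
#' @param curvature magnitude of the residual-curvature (second-order
#'   Hessian) term at the optimum, relative to the largest GN eigenvalue
#'   (default 1; only active when `residual_norm_at_opt > 0`).
#' @return list of class `"tr_nls_problem"` with `objective` (a
#'   [tr_objective()]), `theta_true`, `domain`, `residual_fn`, `jacobian_fn`
#'   and the generating matrices.
#' @export
make_nls_problem <- function(n_par, n_res, residual_norm_at_opt = 0,
                             spectrum_decades = 0, domain = NULL,
                             seed = 1L, alpha = 0.3, curvature = 1) {
  stopifnot(n_res >= n_par, n_par >= 1, residual_norm_at_opt >= 0,
            alpha >= 0, alpha < 1)
  if (residual_norm_at_opt > 0 && n_res <= n_par)
    stop("a non-zero residual at the optimum requires n_res > n_par")
  if (spectrum_decades > 250)
    stop("requested spectrum exceeds the floating-point range")
  if (is.null(domain)) domain <- search_domain(rep(-3, n_par), rep(3, n_par))
  stopifnot(all(is.finite(domain$lower)), all(is.finite(domain$upper)))
  with_local_seed(seed, {
    theta_true <- domain$lower + (0.25 + 0.5 * stats::runif(n_par)) *
      (domain$upper - domain$lower)
    U <- random_orthonormal(n_res, n_par)
    V <- random_orthonormal(n_par, n_par)
    lam <- if (n_par == 1) 1 else 10^(-spectrum_decades *
                                        (seq_len(n_par) - 1) / (n_par - 1))
    A <- U %*% (sqrt(lam) * t(V))
    c_vec <- rep(0, n_res)
    S <- matrix(0, n_par, n_par)
    if (residual_norm_at_opt > 0) {
      raw <- stats::rnorm(n_res)
      raw <- raw - U %*% crossprod(U, raw)      # project onto null(t(A))
      c_vec <- drop(raw) * residual_norm_at_opt / sqrt(sum(raw^2))
      G <- matrix(stats::rnorm(n_par * n_par), n_par)
      S <- crossprod(G)
      S <- S / max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    }
  })
  c2 <- sum(c_vec^2)
  qcoef <- if (c2 > 0) curvature * c_vec / c2 else rep(0, n_res)
  warp <- function(theta) theta + alpha * sin(theta - theta_true)
  dwarp <- function(theta) 1 + alpha * cos(theta - theta_true)
  w_true <- warp(theta_true)
  residual_fn <- function(theta) {
    d <- theta - theta_true
    drop(A %*% (warp(theta) - w_true)) + c_vec +
      qcoef * (0.5 * sum(d * drop(S %*% d)))
  }
  jacobian_fn <- function(theta) {
    d <- theta - theta_true
    A * rep(dwarp(theta), each = n_res) + outer(qcoef, drop(S %*% d))
  }
  objective <- tr_objective(function(theta) {
    r <- residual_fn(theta)
    jr <- jacobian_fn(theta)
    list(f = 0.5 * sum(r^2), g = drop(crossprod(jr, r)), r = r, jr = jr)
  })
  structure(list(objective = objective, theta_true = theta_true,
                 domain = domain, residual_fn = residual_fn,
                 jacobian_fn = jacobian_fn, A = A, c = c_vec, S = S,
                 alpha = alpha, curvature = curvature, seed = seed),
            class = "tr_nls_problem")
}

#' Two-species conversion model with Gaussian noise
#'
#' Closed-form fixture for a reversible conversion reaction
#' \eqn{X_1 \rightleftharpoons X_2} under mass-action kinetics,
#' \eqn{\dot x_1 = -k_1 x_1 + k_2 x_2}, \eqn{\dot x_2 = k_1 x_1 - k_2 x_2},
#' observed as \eqn{y = x_2} at the given times. Synthetic data are drawn
#' with additive, independent Gaussian noise. Rates are estimated on the
#' log10 scale; optionally the noise standard deviation is an extra (free)
#' parameter, which makes the likelihood non-least-squares and exercises
#' the GNe error-residual correction.
#'
#' @param rates true rate constants `c(k1, k2)`, positive.
#' @param x0 initial abundances `c(x1_0, x2_0)`.
#' @param times non-negative observation times.
#' @param sigma noise standard deviation used to simulate the data.
#' @param estimate_sigma if `TRUE` the noise scale is a third parameter
#'   `theta[3] = sigma` (natural scale) with gradient contributions in the
#'   objective; if `FALSE` (default) `sigma` is fixed and known.
#' @param seed integer seed for the noise draw.
#' @return list of class `"tr_conversion_model"` with `objective`,
#'   `theta_true` (log10 rates, plus sigma if estimated), `domain`, `data`
#'   (data frame with `time`, `y`, `ybar`, `sigma`), and `trajectory(times,
#'   k1, k2)` giving the closed-form observable.
#' @export
conversion_model <- function(rates = c(2, 0.5), x0 = c(1, 0),
                             times = seq(0, 5, length.out = 16),
                             sigma = 0.02, estimate_sigma = FALSE,
                             seed = 1L) {
  stopifnot(length(rates) == 2, all(rates > 0), all(times >= 0), sigma > 0)
  total <- sum(x0)
  trajectory <- function(times, k1, k2) {
    ksum <- k1 + k2
    x1_eq <- k2 * total / ksum
    x1 <- x1_eq + (x0[1] - x1_eq) * exp(-ksum * times)
    total - x1                                  # observable y = x2
  }
  y_true <- trajectory(times, rates[1], rates[2])
  ybar <- with_local_seed(seed,
    y_true + stats::rnorm(length(times), sd = sigma))
  dat <- data.frame(time = times, y = y_true, ybar = ybar, sigma = sigma)

  # analytic observable sensitivities d y / d k
  dy_dk <- function(k1, k2) {
    ksum <- k1 + k2
    x1_eq <- k2 * total / ksum
    E <- exp(-ksum * times)
    d_eq <- c(-k2 * total / ksum^2, k1 * total / ksum^2)  # d x1_eq / d k
    dx1 <- cbind(
      d_eq[1] * (1 - E) + (x0[1] - x1_eq) * (-times * E),
      d_eq[2] * (1 - E) + (x0[1] - x1_eq) * (-times * E))
    -dx1                                        # d y / d k = -d x1 / d k
  }

  n_obs <- length(times)
  fn <- function(theta) {
    k <- 10^theta[1:2]
    if (!all(is.finite(k)) || any(k <= 0)) return(list(ok = FALSE))
    sig <- if (estimate_sigma) theta[3] else sigma
    if (sig <= 0) return(list(ok = FALSE))
    y <- trajectory(times, k[1], k[2])
    r <- (ybar - y) / sig
    dy <- dy_dk(k[1], k[2]) * rep(k * log(10), each = n_obs)  # log10 chain
    jr_k <- -dy / sig
    sig_vec <- rep(sig, n_obs)
    if (estimate_sigma) {
      jr <- cbind(jr_k, -r / sig)
      dsig <- cbind(0, 0, rep(1, n_obs))
      g <- drop(crossprod(jr, r)) + c(0, 0, n_obs / sig)
    } else {
      jr <- jr_k
      dsig <- NULL
      g <- drop(crossprod(jr, r))
    }
    list(f = nll_from_residuals(ybar, y, sig_vec), g = g, r = r, jr = jr,
         sigma = sig_vec, dsigma = dsig, ok = TRUE)
  }
  theta_true <- c(log10(rates), if (estimate_sigma) sigma)
  domain <- if (estimate_sigma)
    search_domain(c(-3, -3, 1e-4), c(3, 3, 1))
  else
    search_domain(c(-3, -3), c(3, 3))
  structure(list(objective = tr_objective(fn), theta_true = theta_true,
                 domain = domain, data = dat, trajectory = trajectory,
                 rates = rates, x0 = x0, sigma = sigma,
                 estimate_sigma = estimate_sigma, seed = seed),
            class = "tr_conversion_model")
}

#' Classic curved-valley least-squares test problem
#'
#' The standard two-parameter banana-valley function in least-squares form,
#' residuals `c(10 * (theta2 - theta1^2), 1 - theta1)` and objective
#' `0.5 * ||r||^2`, with minimum 0 at `(1, 1)`; bounded to `[-2, 2]^2` by
#' default.
#'
#' @param domain optional [search_domain()] (default `[-2, 2]^2`).
#' @return list with `objective`, `theta_true`, `domain`, `start` (the
#'   customary start point `(-1.2, 1)`).
#' @export
rosenbrock_problem <- function(domain = NULL) {
  if (is.null(domain)) domain <- search_domain(c(-2, -2), c(2, 2))
  fn <- function(theta) {
    r <- c(10 * (theta[2] - theta[1]^2), 1 - theta[1])
    jr <- matrix(c(-20 * theta[1], 10, -1, 0), 2, 2, byrow = TRUE)
    list(f = 0.5 * sum(r^2), g = drop(crossprod(jr, r)), r = r, jr = jr)
  }
  list(objective = tr_objective(fn), theta_true = c(1, 1), domain = domain,
       start = c(-1.2, 1))
}

#' Convex quadratic test problem in least-squares form
#'
#' `f(theta) = 0.5 * (theta - a)' Q (theta - a)` written with affine
#' residuals `r = L (theta - a)`, `Q = L'L`, so the Gauss-Newton matrix is
#' the exact Hessian `Q`.
#'
#' @param a minimizer vector.
#' @param Q symmetric positive definite matrix (default identity).
#' @return list with `objective`, `theta_true = a`, `domain` (unbounded).
#' @export
quadratic_problem <- function(a, Q = NULL) {
  n <- length(a)
  if (is.null(Q)) Q <- diag(n)
  ch <- chol(Q)
  fn <- function(theta) {
    r <- drop(ch %*% (theta - a))
    list(f = 0.5 * sum(r^2), g = drop(crossprod(ch, r)), r = r, jr = ch)
  }
  list(objective = tr_objective(fn), theta_true = a,
       domain = unbounded_domain(n))
}

#' Uniform start points in a box
#'
#' Samples `n_starts` points, uniform per coordinate and strictly interior;
#' reproducible by seed.
#'
#' @param domain a [search_domain()] with finite bounds.
#' @param n_starts number of points.
#' @param seed integer seed.
#' @return matrix `n_starts` by `domain$n`, one start point per row.
#' @export
sample_startpoints <- function(domain, n_starts, seed = 1L) {
  stopifnot(inherits(domain, "tr_domain"), n_starts >= 1)
  if (!all(is.finite(domain$lower)) || !all(is.finite(domain$upper)))
    stop("sampling start points requires finite bounds on every coordinate")
  pts <- with_local_seed(seed, {
    u <- matrix(stats::runif(n_starts * domain$n), n_starts, domain$n)
    sweep(sweep(u, 2, domain$upper - domain$lower, "*"), 2, domain$lower,
          "+")
  })
  margin <- 1e-8 * (domain$upper - domain$lower)
  for (j in seq_len(domain$n)) {
    pts[, j] <- pmin(pmax(pts[, j], domain$lower[j] + margin[j]),
                     domain$upper[j] - margin[j])
  }
  pts
}
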