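#' Gaussian negative log-likelihood from standardized residual ingredients
#'
#' Computes the negative log-likelihood of independent Gaussian measurements,
#' \deqn{J = \frac{1}{2}\sum_k \left[\log(2\pi\sigma_k^2) +
#'   \left(\frac{\bar y_k - y_k}{\sigma_k}\right)^2\right],}
#' the standard objective for maximum-likelihood calibration of dynamical
#' models under additive, independent, normally distributed noise. The double
#' sum over observables and time points is flattened into a single residual
#' index.
#'
#' @param ybar numeric vector of measured values.
#' @param y numeric vector of model-predicted values (same length as `ybar`).
#' @param sigma numeric vector of noise standard deviations, all positive.
#' @return scalar objective value.
#' @examples
#' nll_from_residuals(1, 1, 1)          # 0.5 * log(2 * pi)
#' nll_from_residuals(c(1, 2), c(0, 0), c(1, 1))
#' @export
nll_from_residuals <- function(ybar, y, sigma) {
  if (length(ybar) != length(y) || length(y) != length(sigma))
    stop("ybar, y and sigma must have equal lengths")
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("all noise standard deviations sigma must be positive and finite")
  sum(0.5 * (log(2 * pi * sigma^2) + ((ybar - y) / sigma)^2))
}

#' Box search domain
#'
#' Defines the rectangular parameter domain for bound-constrained
#' optimization. Bounds may be infinite; each lower bound must be strictly
#' smaller than the corresponding upper bound.
#'
#' @param lower numeric vector of lower bounds (may contain `-Inf`).
#' @param upper numeric vector of upper bounds (may contain `Inf`).
#' @return an object of class `"tr_domain"` with elements `lower`, `upper`,
#'   and `n` (dimension).
#' @export
search_domain <- function(lower, upper) {
  n <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(is.na(lower)) || any(is.na(upper)))
    stop("bounds must not contain NA")
  if (!all(lower < upper))
    stop("every lower bound must be strictly smaller than its upper bound")
  structure(list(lower = lower, upper = upper, n = n), class = "tr_domain")
}

#' Unbounded search domain of dimension n
#' @param n dimension.
#' @return a `"tr_domain"` with all bounds infinite.
#' @export
unbounded_domain <- function(n) search_domain(rep(-Inf, n), rep(Inf, n))

as_domain <- function(domain, n) {
  if (is.null(domain)) return(unbounded_domain(n))
  if (!inherits(domain, "tr_domain")) stop("domain must be a 'tr_domain'")
  if (domain$n != n) stop("domain dimension does not match parameter length")
  domain
}

#' Test whether a point is strictly inside a box domain
#' @param theta numeric parameter vector.
#' @param domain a [search_domain()].
#' @return logical scalar.
#' @export
is_interior <- function(theta, domain) {
  all(theta > domain$lower) && all(theta < domain$upper)
}

# Pull a point strictly inside the box: coordinates on/past a bound are set
# a relative distance eps inside. Used as the interior backoff for stepback
# candidates (interior method: iterates must never touch the boundary).
force_interior <- function(x, domain, eps = 1e-10) {
  l <- domain$lower
  u <- domain$upper
  width <- ifelse(is.finite(l) & is.finite(u), u - l,
                  pmax(1, abs(ifelse(is.finite(l), l, 0)),
                       abs(ifelse(is.finite(u), u, 0))))
  margin <- eps * width
  x <- ifelse(is.finite(l), pmax(x, l + margin), x)
  x <- ifelse(is.finite(u), pmin(x, u - margin), x)
  x
}

#' Objective-function contract
#'
#' Wraps a user function into the evaluation contract consumed by the
#' optimizer and the Hessian approximation schemes. The wrapped function is
#' called with a parameter vector and must return a list with components:
#'
#' * `f` — scalar objective value,
#' * `g` — gradient vector (same length as the parameters),
#' * `r` — optional residual vector (required by least-squares schemes),
#' * `jr` — optional residual Jacobian, `length(r)` by `length(theta)`,
#' * `sigma` — optional vector of noise standard deviations per residual,
#' * `dsigma` — optional matrix of noise gradients, `length(r)` by
#'   `length(theta)` (enables the error-residual GNe correction),
#' * `ok` — optional logical; `FALSE` signals an evaluation failure (for
#'   ODE models, typically an integration failure).
#'
#' Evaluation errors thrown by `fn`, as well as non-finite `f` or `g`, are
#' converted into `ok = FALSE`; the trust-region loop then treats the
#' iteration as a failed trial and shrinks the radius.
#'
#' @param fn the evaluation function described above.
#' @param hessian optional function `theta -> matrix` supplying an exact
#'   Hessian (only consulted by the pointwise `"EXACT"` scheme if selected).
#' @return an object of class `"tr_objective"`.
#' @export
tr_objective <- function(fn, hessian = NULL) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, hessian = hessian), class = "tr_objective")
}

failed_eval <- function(n) {
  list(f = NA_real_, g = rep(NA_real_, n), r = NULL, jr = NULL,
       sigma = NULL, dsigma = NULL, ok = FALSE)
}

#' Evaluate an objective contract at a parameter vector
#'
#' Calls the wrapped function and normalizes the result; any thrown error or
#' non-finite objective/gradient yields `ok = FALSE`.
#'
#' @param objective a [tr_objective()].
#' @param theta parameter vector.
#' @return list with `f`, `g`, `r`, `jr`, `sigma`, `dsigma`, `ok`.
#' @export
eval_objective <- function(objective, theta) {
  stopifnot(inherits(objective, "tr_objective"))
  n <- length(theta)
  res <- tryCatch(objective$fn(theta), error = function(e) NULL)
  if (is.null(res) || !is.list(res)) return(failed_eval(n))
  if (!is.null(res$ok) && !isTRUE(res$ok)) return(failed_eval(n))
  f <- res$f
  g <- res$g
  if (is.null(f) || is.null(g) || !is.finite(f) || !all(is.finite(g)))
    return(failed_eval(n))
  if (length(g) != n) stop("gradient length does not match parameter length")
  r <- res$r
  jr <- res$jr
  if (!is.null(r) && !is.null(jr)) {
    jr <- as.matrix(jr)
    if (nrow(jr) != length(r) || ncol(jr) != n)
      stop("residual Jacobian must be length(r) x length(theta)")
    if (!all(is.finite(r)) || !all(is.finite(jr))) return(failed_eval(n))
  }
  list(f = as.numeric(f), g = as.numeric(g), r = r, jr = jr,
       sigma = res$sigma, dsigma = res$dsigma, ok = TRUE)
}
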