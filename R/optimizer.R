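#' Optimizer options
#'
#' Settings for [tr_minimize()]. The radius-update rule follows the
#' interior-reflective variant: the radius doubles when the prediction is
#' accurate (`rho > 0.75`) and the step lies at the trust-region edge
#' (`norm > 0.9 * delta`); it is set to `min(delta, norm(p)) / 4` when the
#' prediction is inaccurate (`rho < 0.25`) or the trial evaluation fails.
#'
#' @param scheme Hessian approximation scheme: one of `"GN"`, `"GNe"`,
#'   `"BFGS"`, `"SR1"`, `"SSM"`, `"TSSM"`, `"FX"`, `"GNSBFGS"`, `"HYBRID"`.
#' @param subspace `"2D"` (gradient/Newton plane, default) or `"ND"` (exact
#'   full-space solve).
#' @param max_reflections `1` or `Inf` boundary reflections for the
#'   reflected stepback.
#' @param mu step-acceptance threshold on the prediction ratio (default 0;
#'   acceptance is strict, `rho > mu`).
#' @param step_tol convergence tolerance on the step norm (default `1e-6`).
#' @param max_iter iteration cap (default `1e5`).
#' @param initial_radius initial trust-region radius in scaled coordinates.
#' @param radius_min radius underflow threshold; below it optimization
#'   terminates with status `"failure"`.
#' @param n_hybrid consecutive radius stalls before the hybrid scheme
#'   switches to BFGS (default 50).
#' @param C error-residual offset for the GNe correction (default 50).
#' @param eps_fx Fletcher-Xu residual-decrease threshold (default 0.2).
#' @param eps_gnsbfgs GNSBFGS curvature threshold (default `1e-6`).
#' @param diagnostics compute per-iteration condition-number and eigenvalue
#'   flags for the trace (default `TRUE`; adds two decompositions per
#'   iteration).
#' @return list of class `"tr_options"`.
#' @export
tr_options <- function(scheme = "GN", subspace = c("2D", "ND"),
                       max_reflections = Inf, mu = 0,
                       step_tol = 1e-6, max_iter = 1e5,
                       initial_radius = 1, radius_min = 1e-16,
                       n_hybrid = 50, C = 50, eps_fx = 0.2,
                       eps_gnsbfgs = 1e-6, diagnostics = TRUE) {
  scheme <- match.arg(scheme, tr_schemes)
  subspace <- match.arg(subspace)
  stopifnot(mu >= 0, step_tol > 0, max_iter >= 1, initial_radius > 0,
            max_reflections >= 1)
  structure(list(scheme = scheme, subspace = subspace,
                 max_reflections = max_reflections, mu = mu,
                 step_tol = step_tol, max_iter = as.integer(max_iter),
                 initial_radius = initial_radius, radius_min = radius_min,
                 n_hybrid = n_hybrid, C = C, eps_fx = eps_fx,
                 eps_gnsbfgs = eps_gnsbfgs, diagnostics = diagnostics),
            class = "tr_options")
}

#' Prediction-accuracy ratio
#'
#' `rho = dJ / pred` when the predicted decrease is positive; when the model
#' predicts an increase (`pred <= 0`, possible through the bound-handling
#' augmentation) `rho` is set to 0, which prevents spurious acceptance and
#' radius growth when both quantities are negative.
#'
#' @param dJ actual objective decrease `f_old - f_trial`.
#' @param pred predicted decrease `-m(p)`.
#' @return scalar ratio.
#' @export
step_ratio <- function(dJ, pred) {
  if (!is.finite(dJ) || !is.finite(pred))
    stop("step_ratio requires finite inputs")
  if (pred > 0) dJ / pred else 0
}

#' Trust-region radius update
#'
#' @param delta current radius.
#' @param rho prediction ratio from [step_ratio()].
#' @param step_norm norm of the proposed step (scaled coordinates).
#' @param eval_failed logical; trial evaluation failure.
#' @return list with `delta` (new radius) and `updated` (logical; whether
#'   the radius changed — this flag drives the hybrid stall counter).
#' @export
update_radius <- function(delta, rho, step_norm, eval_failed = FALSE) {
  stopifnot(delta > 0)
  new_delta <- delta
  if (eval_failed) {
    new_delta <- min(delta, step_norm) / 4
  } else if (rho > 0.75 && step_norm > 0.9 * delta) {
    new_delta <- 2 * delta
  } else if (rho < 0.25) {
    new_delta <- min(delta, step_norm) / 4
  }
  list(delta = new_delta, updated = new_delta != delta)
}

#' Convergence check
#'
#' Step-tolerance convergence when the proposed step norm drops below
#' `step_tol`; iteration-cap status at `max_iter`.
#'
#' @param step_norm norm of the current step.
#' @param iteration current iteration number.
#' @param options a [tr_options()].
#' @return `"step-tolerance"`, `"max-iterations"`, or `NULL`.
#' @export
check_convergence <- function(step_norm, iteration, options) {
  if (is.finite(step_norm) && step_norm < options$step_tol)
    return("step-tolerance")
  if (iteration >= options$max_iter) return("max-iterations")
  NULL
}

empty_trace_row <- function() {
  data.frame(iteration = integer(), f = numeric(), gnorm = numeric(),
             delta = numeric(), rho = numeric(), step_norm = numeric(),
             accepted = logical(), step_kind = character(),
             radius_updated = logical(), hessian_updated = logical(),
             singular_hessian = logical(), negative_eigenvalue = logical(),
             eval_failed = logical(), boundary_constrained = logical(),
             hybrid_switched = logical(), stringsAsFactors = FALSE)
}

#' Interior-reflective trust-region minimization
#'
#' Minimizes a smooth objective over a box domain. Each iteration builds the
#' Coleman-Li scaled quadratic model (Hessian from the selected
#' approximation scheme), solves the trust-region subproblem over the 2D
#' subspace or the full space, applies reflection / truncation /
#' constrained-Cauchy stepback when the proposal leaves the box, accepts the
#' trial if the prediction ratio exceeds `mu`, and adapts the radius.
#' Exactly one objective (and gradient) evaluation is spent per iteration,
#' so the gradient-evaluation count equals the iteration count.
#'
#' @param objective a [tr_objective()].
#' @param theta0 start vector, strictly inside `domain`.
#' @param domain a [search_domain()] (default: unbounded).
#' @param options a [tr_options()].
#' @return object of class `"tr_result"`: list with `theta`, `f`, `status`
#'   (`"step-tolerance"`, `"max-iterations"`, or `"failure"`),
#'   `iterations`, `n_grad`, and `trace` (one data-frame row per iteration
#'   with the objective value, radius, ratio, acceptance and the numerical
#'   flags: singular transformed Hessian, negative eigenvalue of the
#'   untransformed approximation, evaluation failure, boundary handling,
#'   hybrid switch state).
#' @export
tr_minimize <- function(objective, theta0, domain = NULL,
                        options = tr_options()) {
  theta0 <- as.numeric(theta0)
  n <- length(theta0)
  domain <- as_domain(domain, n)
  if (!is_interior(theta0, domain))
    stop("theta0 must be strictly inside the search domain")
  ev <- eval_objective(objective, theta0)
  if (!ev$ok) {
    return(structure(list(theta = theta0, f = NA_real_, status = "failure",
                          iterations = 0L, n_grad = 0L,
                          trace = empty_trace_row()),
                     class = "tr_result"))
  }
  hs <- hessian_state_init(options$scheme, n, options, ev)
  theta <- theta0
  f <- ev$f
  g <- ev$g
  delta <- options$initial_radius
  rows <- vector("list", min(options$max_iter, 4096L))
  status <- "max-iterations"
  k <- 0L

  while (k < options$max_iter) {
    k <- k + 1L
    B <- hs$B
    sc <- scaling_vector(theta, g, domain)
    tm <- transform_model(B, g, sc$v, sc$dv)

    singular <- FALSE
    negeig <- FALSE
    if (options$diagnostics) {
      singular <- is_numerically_singular(tm$B_hat)
      negeig <- has_negative_eigenvalue(B)
    }

    sub <- if (options$subspace == "2D")
      solve_tr_2d(tm$g_hat, tm$B_hat, delta)
    else
      solve_tr_nd(tm$g_hat, tm$B_hat, delta)
    p <- tm$D * sub$p

    boundary <- !is_interior(theta + p, domain)
    if (!boundary || sub$norm == 0) {
      cand <- step_candidate(p, sub$kind, g, tm$B_eff)
    } else {
      cands <- list(
        reflect_step(p, theta, domain, g, tm$B_eff, options$max_reflections),
        truncate_step(p, theta, domain, g, tm$B_eff),
        constrained_cauchy(g, tm$B_eff, theta, domain, delta, tm$D))
      cand <- select_step(cands)
    }
    pred <- -cand$model_value
    step_norm_scaled <- sqrt(sum((cand$p / tm$D)^2))
    step_norm <- cand$norm

    trial <- theta + cand$p
    ev_t <- eval_objective(objective, trial)
    failed <- !ev_t$ok
    rho <- if (failed) 0 else step_ratio(f - ev_t$f, pred)
    accepted <- !failed && rho > options$mu && pred > 0

    ru <- update_radius(delta, rho, step_norm_scaled, failed)
    hs <- hessian_state_radius(hs, ru$updated)

    hess_updated <- FALSE
    if (accepted) {
      acc <- hessian_state_accept(hs, cand$p, ev_t$g - g, ev_t)
      hs <- acc$state
      hess_updated <- acc$updated
      theta <- trial
      f <- ev_t$f
      g <- ev_t$g
    }

    if (k > length(rows)) rows <- c(rows, vector("list", length(rows)))
    rows[[k]] <- data.frame(
      iteration = k, f = f, gnorm = sqrt(sum(g^2)), delta = delta,
      rho = rho, step_norm = step_norm, accepted = accepted,
      step_kind = cand$kind, radius_updated = ru$updated,
      hessian_updated = hess_updated, singular_hessian = singular,
      negative_eigenvalue = negeig, eval_failed = failed,
      boundary_constrained = boundary,
      hybrid_switched = isTRUE(hs$hybrid$switched),
      stringsAsFactors = FALSE)

    conv <- check_convergence(step_norm, k, options)
    if (!is.null(conv)) { status <- conv; break }
    delta <- ru$delta
    if (delta < options$radius_min) { status <- "failure"; break }
  }

  trace <- do.call(rbind, rows[seq_len(k)])
  if (is.null(trace)) trace <- empty_trace_row()
  structure(list(theta = theta, f = f, status = status, iterations = k,
                 n_grad = k, trace = trace),
            class = "tr_result")
}

#' @export
print.tr_result <- function(x, ...) {
  cat("Trust-region result\n")
  cat(sprintf("  status:     %s after %d iterations\n", x$status,
              x$iterations))
  cat(sprintf("  objective:  %.8g\n", x$f))
  cat(sprintf("  theta:      %s\n",
              paste(signif(x$theta, 6), collapse = ", ")))
  invisible(x)
}
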