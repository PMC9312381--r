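#' Hessian approximation schemes
#'
#' @description
#' Pure matrix-level implementations of the Hessian approximation schemes
#' used by [tr_minimize()]:
#'
#' * `gauss_newton()` — GN, the outer-product-of-residual-gradients
#'   approximation \eqn{B = J_r^T J_r}; exact for affine standardized
#'   residuals, positive semi-definite, ignores residual curvature.
#' * `gauss_newton_e()` — GNe, GN plus the error-residual correction that
#'   keeps a least-squares structure when the noise scale depends on
#'   parameters: each residual contributes
#'   \eqn{\nabla\sigma \nabla\sigma^T / (\sigma^2 (2\log\sigma + C))}.
#' * `bfgs_update()` / `sr1_update()` — iterative rank-2 / rank-1 secant
#'   updates; BFGS preserves positive semi-definiteness under the curvature
#'   condition \eqn{z^T s > 0} (updates violating it are skipped), SR1 can
#'   produce indefinite approximations.
#' * `ssm_update()` / `tssm_update()` — structured secant methods that add
#'   an iteratively BFGS-updated matrix `A` to GNe to model the residual
#'   curvature term of the true Hessian (TSSM scales `A` by the residual
#'   norm).
#' * `fx_update()` — the Fletcher–Xu hybrid: BFGS-update the carried matrix
#'   when the relative decrease of the residual norm falls below `eps_fx`
#'   (a non-zero-residual signature), otherwise restart from a fresh GNe.
#' * `gnsbfgs_update()` — Gauss–Newton structured BFGS: BFGS-update `A`
#'   with the scaled structured secant vector when its curvature estimate
#'   exceeds `eps`, else fall back to `GNe + ||r|| I`; always positive
#'   semi-definite.
#'
#' All returned matrices are symmetrized against floating-point drift.
#'
#' @name hessian_schemes
NULL

symmetrize <- function(M) (M + t(M)) / 2

#' @rdname hessian_schemes
#' @param jr residual Jacobian (`n_res` by `n_par`), rows are residual
#'   gradients.
#' @return `gauss_newton()`: symmetric PSD matrix `t(jr) %*% jr`.
#' @export
gauss_newton <- function(jr) {
  jr <- as.matrix(jr)
  if (!all(is.finite(jr))) stop("residual Jacobian must be finite")
  symmetrize(crossprod(jr))
}

#' @rdname hessian_schemes
#' @param sigma noise standard deviations per residual.
#' @param dsigma noise gradient matrix (`n_res` by `n_par`); row k is
#'   the parameter gradient of `sigma[k]`. `NULL` means parameter-independent
#'   noise (correction vanishes).
#' @param C error-residual offset; must satisfy `2*log(sigma) + C > 0` for
#'   every residual so the error residuals stay real-valued.
#' @return `gauss_newton_e()`: symmetric PSD matrix (GN term plus correction).
#' @export
gauss_newton_e <- function(jr, sigma, dsigma = NULL, C = 50) {
  B <- gauss_newton(jr)
  if (is.null(dsigma)) return(B)
  dsigma <- as.matrix(dsigma)
  sigma <- as.numeric(sigma)
  if (nrow(dsigma) != length(sigma))
    stop("dsigma must have one row per noise value")
  denom <- sigma^2 * (2 * log(sigma) + C)
  bad <- which(2 * log(sigma) + C <= 0)
  if (length(bad))
    stop(sprintf("2*log(sigma) + C <= 0 for residual(s) %s; increase C",
                 paste(bad, collapse = ", ")))
  corr <- crossprod(dsigma / sqrt(denom))
  symmetrize(B + corr)
}

# BFGS delta term with the relative curvature safeguard. Returns the update
# matrix (zero when skipped) plus the skip flag; building block for BFGS
# proper and for the structured schemes' inner updates.
bfgs_delta <- function(M, s, z) {
  zs <- sum(z * s)
  if (!(zs > .Machine$double.eps * sqrt(sum(z^2)) * sqrt(sum(s^2))))
    return(list(delta = matrix(0, length(s), length(s)), skipped = TRUE))
  Ms <- drop(M %*% s)
  sMs <- sum(s * Ms)
  if (sMs == 0) {
    warning("degenerate BFGS denominator s'Ms = 0; update skipped")
    return(list(delta = matrix(0, length(s), length(s)), skipped = TRUE))
  }
  list(delta = tcrossprod(z) / zs - tcrossprod(Ms) / sMs, skipped = FALSE)
}

#' @rdname hessian_schemes
#' @param M current symmetric approximation matrix.
#' @param s accepted step vector (parameter difference).
#' @param z gradient difference vector (or a scheme-specific secant vector).
#' @return `bfgs_update()` / `sr1_update()`: list with `B` (updated matrix)
#'   and `skipped` (logical; `TRUE` when the safeguard rejected the update
#'   and `B` is `M` unchanged).
#' @export
bfgs_update <- function(M, s, z) {
  if (all(s == 0)) stop("step s must be nonzero")
  upd <- bfgs_delta(M, s, z)
  list(B = symmetrize(M + upd$delta), skipped = upd$skipped)
}

#' @rdname hessian_schemes
#' @export
sr1_update <- function(M, s, z) {
  if (all(s == 0)) stop("step s must be nonzero")
  u <- z - drop(M %*% s)
  denom <- sum(u * s)
  if (abs(denom) <= 1e-8 * sqrt(sum(s^2)) * sqrt(sum(u^2)) || denom == 0)
    return(list(B = M, skipped = TRUE))
  list(B = symmetrize(M + tcrossprod(u) / denom), skipped = FALSE)
}

#' Structured secant vector z#
#'
#' `z# = (Jr_new - Jr_old)^T r_new`, the secant vector targeting the
#' residual-curvature term shared by the SSM, TSSM and GNSBFGS schemes.
#'
#' @param jr_new,jr_old residual Jacobians at the new and old iterate.
#' @param r_new residual vector at the new iterate.
#' @return numeric vector of length `n_par`.
#' @export
structured_secant <- function(jr_new, jr_old, r_new) {
  drop(crossprod(jr_new - jr_old, r_new))
}

#' @rdname hessian_schemes
#' @param A current auxiliary (residual-curvature) matrix.
#' @param z_sharp structured secant vector from [structured_secant()].
#' @param gne_new GNe matrix evaluated at the new iterate.
#' @return `ssm_update()` / `tssm_update()` / `gnsbfgs_update()`: list with
#'   `B` (the full approximation), `A` (updated auxiliary matrix) and
#'   `skipped` or `branch` bookkeeping.
#' @export
ssm_update <- function(A, s, z_sharp, gne_new) {
  upd <- bfgs_delta(gne_new + A, s, z_sharp)
  A_new <- symmetrize(A + upd$delta)
  list(B = symmetrize(gne_new + A_new), A = A_new, skipped = upd$skipped)
}

#' @rdname hessian_schemes
#' @param r_new_norm,r_old_norm residual norms at the new and old iterate.
#' @export
tssm_update <- function(A, s, z_sharp, gne_new, r_new_norm, r_old_norm) {
  if (r_old_norm <= 0 || r_new_norm == 0) {
    # scaling undefined (old) or the ||r|| factor kills A (new): plain GNe
    return(list(B = symmetrize(gne_new), A = A, skipped = TRUE))
  }
  z_dagger <- drop(gne_new %*% s) + z_sharp * (r_new_norm / r_old_norm)
  upd <- bfgs_delta(gne_new + r_new_norm * A, s, z_dagger)
  A_new <- symmetrize(A + upd$delta / r_new_norm)
  list(B = symmetrize(gne_new + r_new_norm * A_new), A = A_new,
       skipped = upd$skipped)
}

#' @rdname hessian_schemes
#' @param B_fx carried FX matrix from the previous iteration.
#' @param eps_fx relative residual-norm decrease below which the problem is
#'   treated as non-zero-residual and the BFGS branch is taken (default 0.2,
#'   the originally recommended value).
#' @return `fx_update()`: list with `B` (also the next carried matrix) and
#'   `branch` (`"bfgs"` or `"gne"`).
#' @export
fx_update <- function(B_fx, s, z, gne_new, r_new_norm, r_old_norm,
                      eps_fx = 0.2) {
  take_bfgs <- r_old_norm > 0 &&
    (r_old_norm - r_new_norm) / r_old_norm < eps_fx
  if (take_bfgs) {
    upd <- bfgs_update(B_fx, s, z)
    list(B = upd$B, branch = "bfgs", skipped = upd$skipped)
  } else {
    list(B = symmetrize(gne_new), branch = "gne", skipped = FALSE)
  }
}

#' @rdname hessian_schemes
#' @param eps curvature threshold of the GNSBFGS switch test
#'   `(z_diamond' s) / (s' s) > eps` (default `1e-6`, the originally
#'   recommended value).
#' @export
gnsbfgs_update <- function(A, s, z_sharp, gne_new, r_new_norm, r_old_norm,
                           eps = 1e-6) {
  if (all(s == 0)) stop("step s must be nonzero")
  if (r_old_norm <= 0) stop("r_old_norm must be positive")
  z_diamond <- z_sharp * (r_new_norm / r_old_norm)
  tst <- sum(z_diamond * s) / sum(s * s)
  if (tst > eps) {
    upd <- bfgs_delta(A, s, z_diamond)
    A_new <- symmetrize(A + upd$delta)
    list(B = symmetrize(gne_new + A_new), A = A_new, branch = "structured",
         skipped = upd$skipped)
  } else {
    list(B = symmetrize(gne_new + r_new_norm * diag(length(s))), A = A,
         branch = "scaled-identity", skipped = FALSE)
  }
}

## ---------------------------------------------------------------------------
## Hybrid switching scheme: GN while it works, BFGS for the endgame.
## ---------------------------------------------------------------------------

#' Hybrid GN-to-BFGS switching scheme
#'
#' @description
#' `hybrid_state()` creates the state for the hybrid switching scheme: the
#' optimizer reports every iteration whether the trust-region radius was
#' updated; after `n_hybrid` consecutive iterations without a radius update
#' the scheme switches permanently from the pointwise GN matrix to a shadow
#' BFGS approximation that has been updated silently on every accepted step
#' since the start.
#'
#' `hybrid_update()` advances the state for one iteration: the stall counter
#' increments when `radius_was_updated` is `FALSE` and resets to zero when
#' `TRUE`; on accepted steps (`s`, `z` non-`NULL`) the shadow matrix receives
#' a BFGS update and the GN matrix is replaced by `gn_matrix`. The element
#' `B` of the returned state is the matrix the optimizer should use next.
#'
#' @param n parameter dimension.
#' @param n_hybrid number of consecutive stalled iterations that triggers
#'   the switch.
#' @param gn0 initial GN matrix (identity if omitted).
#' @return `hybrid_state()`: a list with `B`, `B_gn`, `B_shadow`,
#'   `stall_counter`, `switched`, `n_hybrid`.
#' @export
hybrid_state <- function(n, n_hybrid = 50, gn0 = NULL) {
  if (is.null(gn0)) gn0 <- diag(n)
  list(B = gn0, B_gn = gn0, B_shadow = diag(n), stall_counter = 0L,
       switched = FALSE, n_hybrid = n_hybrid)
}

#' @rdname hybrid_state
#' @param state a [hybrid_state()].
#' @param radius_was_updated logical; whether this iteration changed the
#'   trust-region radius.
#' @param gn_matrix fresh GN(e) matrix at the new iterate (used on accepted
#'   steps before the switch).
#' @param s,z accepted step and gradient difference (`NULL` on rejected
#'   iterations).
#' @export
hybrid_update <- function(state, radius_was_updated, gn_matrix = NULL,
                          s = NULL, z = NULL) {
  if (!is.null(s) && !is.null(z)) {
    state$B_shadow <- bfgs_update(state$B_shadow, s, z)$B
    if (!is.null(gn_matrix)) state$B_gn <- gn_matrix
  }
  if (!state$switched) {
    if (isTRUE(radius_was_updated)) {
      state$stall_counter <- 0L
    } else {
      state$stall_counter <- state$stall_counter + 1L
      if (state$stall_counter >= state$n_hybrid) state$switched <- TRUE
    }
  }
  state$B <- if (state$switched) state$B_shadow else state$B_gn
  state
}

## ---------------------------------------------------------------------------
## Scheme state machine used by the optimizer loop.
## ---------------------------------------------------------------------------

tr_schemes <- c("GN", "GNe", "BFGS", "SR1", "SSM", "TSSM", "FX", "GNSBFGS",
                "HYBRID")

scheme_needs_residuals <- function(scheme) {
  scheme %in% c("GN", "GNe", "SSM", "TSSM", "FX", "GNSBFGS", "HYBRID")
}

# GNe matrix from an evaluation (falls back to plain GN when no noise
# gradients are supplied). Structured schemes always build on GNe.
eval_gne <- function(ev, C) {
  gauss_newton_e(ev$jr, ev$sigma, ev$dsigma, C = C)
}

hessian_state_init <- function(scheme, n, options, ev0) {
  scheme <- match.arg(scheme, tr_schemes)
  if (scheme_needs_residuals(scheme) && (is.null(ev0$r) || is.null(ev0$jr)))
    stop(sprintf("scheme %s requires residuals and a residual Jacobian",
                 scheme))
  st <- list(scheme = scheme, n = n, C = options$C,
             eps_fx = options$eps_fx, eps_gnsbfgs = options$eps_gnsbfgs,
             prev_r = ev0$r, prev_jr = ev0$jr,
             A = NULL, hybrid = NULL, B = NULL)
  st$B <- switch(scheme,
    GN = gauss_newton(ev0$jr),
    GNe = eval_gne(ev0, st$C),
    BFGS = diag(n),
    SR1 = diag(n),
    SSM = { st$A <- matrix(0, n, n); eval_gne(ev0, st$C) },
    TSSM = { st$A <- matrix(0, n, n); eval_gne(ev0, st$C) },
    FX = { st$A <- eval_gne(ev0, st$C); st$A },
    GNSBFGS = {
      st$A <- diag(n)
      symmetrize(eval_gne(ev0, st$C) + sqrt(sum(ev0$r^2)) * diag(n))
    },
    HYBRID = {
      st$hybrid <- hybrid_state(n, options$n_hybrid,
                                gn0 = gauss_newton(ev0$jr))
      st$hybrid$B
    })
  st
}

# Advance the scheme state after an accepted step; returns the state plus
# whether a secant update was actually performed (feeds the trace).
hessian_state_accept <- function(st, s, z, ev_new) {
  updated <- TRUE
  skipped <- FALSE
  switch(st$scheme,
    GN = { st$B <- gauss_newton(ev_new$jr) },
    GNe = { st$B <- eval_gne(ev_new, st$C) },
    BFGS = {
      upd <- bfgs_update(st$B, s, z)
      st$B <- upd$B; skipped <- upd$skipped
    },
    SR1 = {
      upd <- sr1_update(st$B, s, z)
      st$B <- upd$B; skipped <- upd$skipped
    },
    SSM = {
      zs <- structured_secant(ev_new$jr, st$prev_jr, ev_new$r)
      upd <- ssm_update(st$A, s, zs, eval_gne(ev_new, st$C))
      st$B <- upd$B; st$A <- upd$A; skipped <- upd$skipped
    },
    TSSM = {
      zs <- structured_secant(ev_new$jr, st$prev_jr, ev_new$r)
      upd <- tssm_update(st$A, s, zs, eval_gne(ev_new, st$C),
                         sqrt(sum(ev_new$r^2)), sqrt(sum(st$prev_r^2)))
      st$B <- upd$B; st$A <- upd$A; skipped <- upd$skipped
    },
    FX = {
      upd <- fx_update(st$A, s, z, eval_gne(ev_new, st$C),
                       sqrt(sum(ev_new$r^2)), sqrt(sum(st$prev_r^2)),
                       eps_fx = st$eps_fx)
      st$B <- upd$B; st$A <- upd$B; skipped <- isTRUE(upd$skipped)
    },
    GNSBFGS = {
      zs <- structured_secant(ev_new$jr, st$prev_jr, ev_new$r)
      upd <- gnsbfgs_update(st$A, s, zs, eval_gne(ev_new, st$C),
                            sqrt(sum(ev_new$r^2)), sqrt(sum(st$prev_r^2)),
                            eps = st$eps_gnsbfgs)
      st$B <- upd$B; st$A <- upd$A; skipped <- isTRUE(upd$skipped)
    },
    HYBRID = {
      # radius flag is registered separately each iteration; here only the
      # accepted-step part (shadow BFGS + fresh GN) is applied
      st$hybrid$B_shadow <- bfgs_update(st$hybrid$B_shadow, s, z)$B
      st$hybrid$B_gn <- gauss_newton(ev_new$jr)
      st$B <- if (st$hybrid$switched) st$hybrid$B_shadow else st$hybrid$B_gn
    })
  st$prev_r <- ev_new$r
  st$prev_jr <- ev_new$jr
  list(state = st, updated = updated && !skipped)
}

# Register the radius-updated flag (hybrid stall counter); no-op for other
# schemes. Called once per iteration, accepted or not.
hessian_state_radius <- function(st, radius_was_updated) {
  if (st$scheme == "HYBRID") {
    st$hybrid <- hybrid_update(st$hybrid, radius_was_updated)
    st$B <- st$hybrid$B
  }
  st
}
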