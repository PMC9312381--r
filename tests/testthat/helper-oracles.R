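# Independent oracles used across the test files. These deliberately avoid
# the code paths they check (no eigendecomposition-based subproblem logic,
# no scheme state machinery).

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(fn, theta, h = 1e-5) {
  n <- length(theta)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      tpp <- tpm <- tmp <- tmm <- theta
      tpp[i] <- tpp[i] + h; tpp[j] <- tpp[j] + h
      tpm[i] <- tpm[i] + h; tpm[j] <- tpm[j] - h
      tmp[i] <- tmp[i] - h; tmp[j] <- tmp[j] + h
      tmm[i] <- tmm[i] - h; tmm[j] <- tmm[j] - h
      H[i, j] <- H[j, i] <- (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) /
        (4 * h^2)
    }
  }
  H
}

fd_gradient <- function(fn, theta, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1))
}

# Brute-force minimization of q(p) = g'p + p'Bp/2 over ||p|| <= delta:
# dense direction sampling with exact 1-D minimization along each ray,
# refined by derivative-free optimization over the direction vector.
# Covers interior minima because rays are minimized over t in [0, delta].
polar_oracle <- function(g, B, delta, n_dirs = 2000, n_refine = 4) {
  d <- length(g)
  ray_min <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    a <- 0.5 * sum(dir * drop(B %*% dir))
    b <- sum(g * dir)
    ts <- c(0, delta)
    if (a > 0) {
      tstar <- -b / (2 * a)
      if (tstar > 0 && tstar < delta) ts <- c(ts, tstar)
    }
    min(a * ts^2 + b * ts)
  }
  dirs <- matrix(stats::rnorm(n_dirs * d), n_dirs, d)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bb <- drop(dirs %*% g)
  aa <- 0.5 * rowSums((dirs %*% B) * dirs)
  tstar <- ifelse(aa > 0, pmin(pmax(-bb / (2 * aa), 0), delta), delta)
  vals <- pmin(aa * tstar^2 + bb * tstar, aa * delta^2 + bb * delta, 0)
  best <- Inf
  for (k in order(vals)[seq_len(n_refine)]) {
    opt <- stats::optim(dirs[k, ], ray_min, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, opt$value)
  }
  best
}

random_symmetric <- function(n, scale = 1) {
  M <- matrix(stats::rnorm(n * n, sd = scale), n)
  (M + t(M)) / 2
}

random_psd <- function(n, scale = 1) {
  G <- matrix(stats::rnorm(n * n, sd = scale), n)
  crossprod(G)
}

# Cauchy point value: exact minimum of the model along -g within the ball.
cauchy_value <- function(g, B, delta) {
  ng <- sqrt(sum(g^2))
  if (ng == 0) return(0)
  dir <- -g / ng
  a <- 0.5 * sum(dir * drop(B %*% dir))
  b <- sum(g * dir)
  ts <- c(delta, if (a > 0 && -b / (2 * a) < delta) -b / (2 * a))
  min(a * ts^2 + b * ts)
}
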