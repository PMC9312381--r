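test_that("Gauss-Newton matrix is the outer-product sum of residual gradients", {
  expect_equal(gauss_newton(diag(2)), diag(2))
  expect_equal(gauss_newton(matrix(c(1, 2), 1, 2)),
               matrix(c(1, 2, 2, 4), 2))
  expect_error(gauss_newton(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("GN equals the exact Hessian of 0.5*||r||^2 for affine residuals", {
  set.seed(11)
  A <- matrix(rnorm(12), 4, 3)
  b <- rnorm(4)
  fn <- function(theta) 0.5 * sum((drop(A %*% theta) - b)^2)
  theta <- rnorm(3)
  expect_equal(gauss_newton(A), crossprod(A))
  expect_equal(gauss_newton(A), fd_hessian(fn, theta), tolerance = 1e-5)
})

test_that("GNe correction matches hand evaluation and vanishes appropriately", {
  set.seed(2)
  jr <- matrix(rnorm(6), 3, 2)
  sigma <- c(0.5, 1, 2)
  # parameter-independent noise: correction vanishes
  expect_equal(gauss_newton_e(jr, sigma, matrix(0, 3, 2), C = 50),
               gauss_newton(jr))
  expect_equal(gauss_newton_e(jr, sigma, NULL, C = 50), gauss_newton(jr))
  # hand evaluation: single parameter, sigma(theta) = theta at theta = 1,
  # no measurement contribution -> correction 1 / (1 * (0 + 50)) = 0.02
  out <- gauss_newton_e(matrix(0, 1, 1), sigma = 1,
                        dsigma = matrix(1, 1, 1), C = 50)
  expect_equal(out[1, 1], 0.02)
  # large C converges to plain GN
  ds <- matrix(rnorm(6, sd = 0.3), 3, 2)
  near <- gauss_newton_e(jr, sigma, ds, C = 1e6)
  far <- gauss_newton_e(jr, sigma, ds, C = 50)
  expect_lt(max(abs(near - gauss_newton(jr))),
            max(abs(far - gauss_newton(jr))) * 1e-3)
  expect_equal(near, gauss_newton(jr), tolerance = 1e-5)
  # realness condition names the violating residual
  expect_error(gauss_newton_e(jr, c(1e-12, 1, 2), ds, C = 50),
               "residual\\(s\\) 1")
})

test_that("BFGS update satisfies the secant condition and the skip rule", {
  # no-op update: s = z = e1 on the identity
  up <- bfgs_update(diag(2), c(1, 0), c(1, 0))
  expect_equal(up$B, diag(2))
  expect_false(up$skipped)
  # hand example with secant verification
  up <- bfgs_update(diag(2), c(1, 0), c(2, 0))
  expect_equal(up$B, diag(c(2, 1)))
  expect_equal(drop(up$B %*% c(1, 0)), c(2, 0))
  # curvature violation: matrix unchanged, skip flag set
  up <- bfgs_update(diag(2), c(1, 0), c(-1, 0))
  expect_true(up$skipped)
  expect_equal(up$B, diag(2))
  expect_error(bfgs_update(diag(2), c(0, 0), c(1, 0)), "nonzero")
})

test_that("SR1 update satisfies the secant condition and can go indefinite", {
  # z = Ms: zero numerator/denominator, safeguard skips
  up <- sr1_update(diag(2), c(1, 0), c(1, 0))
  expect_true(up$skipped)
  expect_equal(up$B, diag(2))
  # rank-1 build-up from zero
  up <- sr1_update(matrix(0, 2, 2), c(1, 0), c(1, 0))
  expect_equal(up$B, diag(c(1, 0)))
  expect_equal(drop(up$B %*% c(1, 0)), c(1, 0))
  # documented indefinite result
  up <- sr1_update(diag(2), c(1, 0), c(-1, 0))
  expect_equal(up$B, diag(c(-1, 1)))
  expect_true(has_negative_eigenvalue(up$B))
})

test_that("secant condition holds after every performed BFGS/SR1 update", {
  set.seed(33)
  for (i in 1:300) {
    n <- sample(2:5, 1)
    M <- random_symmetric(n)
    s <- rnorm(n)
    z <- rnorm(n)
    ub <- bfgs_update(M, s, z)
    if (!ub$skipped)
      expect_equal(drop(ub$B %*% s), z, tolerance = 1e-9)
    else
      expect_lte(sum(z * s), sqrt(sum(z^2)) * sqrt(sum(s^2)) * 1e-12)
    us <- sr1_update(M, s, z)
    if (!us$skipped)
      expect_equal(drop(us$B %*% s), z, tolerance = 1e-7)
  }
})

test_that("structured secant recursions match a scripted reference", {
  # independent re-implementation of the recursions, written directly from
  # the update formulas, driven over a scripted two-step iterate sequence
  set.seed(4)
  n <- 3
  bfgs_term <- function(M, s, z) {
    if (sum(z * s) <= 0) return(matrix(0, n, n))
    Ms <- drop(M %*% s)
    tcrossprod(z) / sum(z * s) - tcrossprod(Ms) / sum(s * Ms)
  }
  A_ref <- matrix(0, n, n)
  A_pkg <- matrix(0, n, n)
  At_ref <- matrix(0, n, n)
  At_pkg <- matrix(0, n, n)
  jr_old <- matrix(rnorm(12), 4, n)
  r_old <- rnorm(4)
  for (k in 1:4) {
    jr_new <- jr_old + matrix(rnorm(12, sd = 0.3), 4, n)
    r_new <- r_old + rnorm(4, sd = 0.2)
    s <- rnorm(n)
    gne <- crossprod(jr_new)
    zsh <- drop(crossprod(jr_new - jr_old, r_new))
    expect_equal(structured_secant(jr_new, jr_old, r_new), zsh)
    # SSM reference
    A_ref <- A_ref + bfgs_term(gne + A_ref, s, zsh)
    out <- ssm_update(A_pkg, s, zsh, gne)
    A_pkg <- out$A
    expect_equal(out$B, gne + A_ref, tolerance = 1e-10)
    # TSSM reference
    rn <- sqrt(sum(r_new^2)); ro <- sqrt(sum(r_old^2))
    zd <- drop(gne %*% s) + zsh * rn / ro
    At_ref <- At_ref + bfgs_term(gne + rn * At_ref, s, zd) / rn
    outt <- tssm_update(At_pkg, s, zsh, gne, rn, ro)
    At_pkg <- outt$A
    expect_equal(outt$B, gne + rn * At_ref, tolerance = 1e-10)
    jr_old <- jr_new
    r_old <- r_new
  }
})

test_that("structured schemes reduce to GNe when correction terms vanish", {
  set.seed(5)
  jr <- matrix(rnorm(8), 4, 2)
  gne <- crossprod(jr)
  s <- rnorm(2)
  # identical Jacobians and A = 0: z# = 0, SSM output is plain GNe
  out <- ssm_update(matrix(0, 2, 2), s, structured_secant(jr, jr, rnorm(4)),
                    gne)
  expect_equal(out$B, gne)
  expect_equal(out$A, matrix(0, 2, 2))
  # zero new residual: z# = 0 too
  out <- ssm_update(matrix(0, 2, 2), s,
                    structured_secant(jr + 1, jr, rep(0, 4)), gne)
  expect_equal(out$B, gne)
  # TSSM: zero new residual norm kills the ||r|| * A term
  outt <- tssm_update(random_symmetric(2), s, rnorm(2), gne, 0, 1)
  expect_equal(outt$B, gne)
  # TSSM first step from A = 0 equals GNe + ||r|| * delta-term / ||r||
  zsh <- rnorm(2)
  outt <- tssm_update(matrix(0, 2, 2), s, zsh, gne, 1.5, 2)
  zd <- drop(gne %*% s) + zsh * 1.5 / 2
  Ms <- drop(gne %*% s)
  delta <- if (sum(zd * s) > 0)
    tcrossprod(zd) / sum(zd * s) - tcrossprod(Ms) / sum(s * Ms)
  else matrix(0, 2, 2)
  expect_equal(outt$B, gne + delta, tolerance = 1e-12)
})

test_that("Fletcher-Xu branches on the relative residual-norm decrease", {
  set.seed(6)
  jr <- matrix(rnorm(8), 4, 2)
  gne <- crossprod(jr)
  Bfx <- random_psd(2)
  s <- rnorm(2)
  z <- rnorm(2)
  # decrease 0.5 >= eps_fx = 0.2: fresh GNe
  out <- fx_update(Bfx, s, z, gne, 0.5, 1)
  expect_equal(out$B, gne)
  expect_identical(out$branch, "gne")
  # decrease 0.05 < 0.2: BFGS branch on the carried matrix
  out <- fx_update(Bfx, s, z, gne, 0.95, 1)
  expect_identical(out$branch, "bfgs")
  expect_equal(out$B, bfgs_update(Bfx, s, z)$B)
})

test_that("GNSBFGS switches between structured update and scaled identity", {
  set.seed(7)
  jr <- matrix(rnorm(8), 4, 2)
  gne <- crossprod(jr)
  A <- diag(2)
  s <- c(1, 0)
  # orthogonal secant: test value 0 <= eps -> GNe + ||r|| I branch
  out <- gnsbfgs_update(A, s, z_sharp = c(0, 5), gne, 1.3, 1)
  expect_equal(out$B, gne + 1.3 * diag(2))
  expect_equal(out$A, A)
  expect_identical(out$branch, "scaled-identity")
  # strong positive curvature: structured branch, A BFGS-updated with the
  # residual-norm-scaled secant vector
  zsh <- c(2, 1)
  out <- gnsbfgs_update(A, s, zsh, gne, 1.3, 1)
  expect_identical(out$branch, "structured")
  zd <- zsh * 1.3
  expect_equal(out$A, bfgs_update(A, s, zd)$B)
  expect_equal(out$B, gne + out$A)
  # zero new residual: both branches give plain GNe
  expect_equal(gnsbfgs_update(A, s, c(0, 0), gne, 0, 1)$B, gne)
})

test_that("PSD schemes stay positive semi-definite on random states", {
  set.seed(8)
  for (i in 1:150) {
    n <- sample(2:4, 1)
    m <- n + sample(1:3, 1)
    jr <- matrix(rnorm(m * n), m, n)
    sigma <- runif(m, 0.2, 3)
    ds <- matrix(rnorm(m * n, sd = 0.2), m, n)
    s <- rnorm(n)
    z <- rnorm(n)
    gne <- gauss_newton_e(jr, sigma, ds, C = 50)
    mats <- list(
      gauss_newton(jr),
      gne,
      fx_update(random_psd(n), s, z, gne, runif(1, 0, 2),
                runif(1, 0.5, 2))$B,
      gnsbfgs_update(random_psd(n), s, rnorm(n), gne, runif(1, 0, 2),
                     runif(1, 0.5, 2))$B,
      bfgs_update(random_psd(n), s, z)$B)
    for (M in mats) {
      lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(lam), -1e-10 * max(abs(lam)))
    }
  }
})

test_that("hybrid switching fires after n_hybrid consecutive stalls only", {
  gn <- matrix(c(2, 0, 0, 3), 2)
  # radius always updated: counter pinned at zero, output is GN
  st <- hybrid_state(2, n_hybrid = 3, gn0 = gn)
  for (i in 1:10) {
    st <- hybrid_update(st, radius_was_updated = TRUE)
    expect_false(st$switched)
    expect_identical(st$B, gn)
  }
  # three consecutive stalls: switch at the third, permanent thereafter
  st <- hybrid_state(2, n_hybrid = 3, gn0 = gn)
  for (i in 1:2) st <- hybrid_update(st, FALSE)
  expect_false(st$switched)
  st <- hybrid_update(st, FALSE)
  expect_true(st$switched)
  expect_identical(st$B, st$B_shadow)
  st <- hybrid_update(st, TRUE)       # a later radius update cannot revert
  expect_true(st$switched)
  # counter resets on any radius update: F,F,T,F,F,F switches at step 6
  st <- hybrid_state(2, n_hybrid = 3, gn0 = gn)
  seqs <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  switched_at <- NA
  for (i in seq_along(seqs)) {
    st <- hybrid_update(st, seqs[i])
    if (st$switched && is.na(switched_at)) switched_at <- i
  }
  expect_identical(switched_at, 6L)
})

test_that("hybrid output is bitwise GN before the switch, shadow BFGS after", {
  set.seed(9)
  st <- hybrid_state(2, n_hybrid = 2, gn0 = diag(2))
  shadow_ref <- diag(2)
  for (i in 1:4) {
    gn <- random_psd(2)
    s <- rnorm(2)
    z <- rnorm(2)
    shadow_ref <- bfgs_update(shadow_ref, s, z)$B
    st <- hybrid_update(st, radius_was_updated = TRUE, gn_matrix = gn,
                        s = s, z = z)
    expect_identical(st$B, gn)
  }
  st <- hybrid_update(st, FALSE)
  st <- hybrid_update(st, FALSE)
  expect_true(st$switched)
  expect_identical(st$B, shadow_ref)
})
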