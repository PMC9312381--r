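Package: trbox
Title: Interior-Reflective Trust-Region Optimization with Flexible Hessian Approximations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bound-constrained minimization of smooth objective functions,
    in particular negative log-likelihoods arising in dynamical-model
    calibration, using an interior-reflective trust-region method with
    Coleman-Li affine scaling. Provides exact (eigendecomposition-based)
    and two-dimensional-subspace solvers for the trust-region subproblem,
    reflection, truncation and constrained-Cauchy stepback at box bounds,
    and a family of Hessian approximation schemes for least-squares and
    general objectives: Gauss-Newton (GN), error-residual-corrected
    Gauss-Newton (GNe), BFGS, SR1, structured secant methods (SSM, TSSM),
    the Fletcher-Xu hybrid (FX), the Gauss-Newton structured BFGS method
    (GNSBFGS), and a hybrid switching scheme that starts from GN and
    switches permanently to a shadow BFGS approximation once the
    trust-region radius stalls. Includes multistart drivers, per-iteration
    trace diagnostics, success-count/convergence-rate/performance metrics,
    and synthetic nonlinear least-squares and mass-action conversion
    fixtures for testing optimizer behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
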