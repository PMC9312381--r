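---
title: "Interior-reflective trust-region optimization with flexible Hessian approximations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interior-reflective trust-region optimization with flexible Hessian approximations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbox)
```

## The estimation problem

`trbox` targets bound-constrained maximum-likelihood estimation as it
arises in the calibration of dynamical models of biochemical networks:
a model predicts observables $y_i(t_j, \theta)$, measurements
$\bar y_{ij}$ carry additive, independent Gaussian noise with standard
deviations $\sigma_{ij}(\theta)$, and the parameters $\theta$ live in a box
$\Theta = \prod_i (l_i, u_i)$ with possibly infinite bounds. The objective
is the negative log-likelihood

$$J(\theta) = \frac{1}{2} \sum_{i,j} \left[ \log\!\big(2\pi\sigma_{ij}^2(\theta)\big)
  + \left(\frac{\bar y_{ij} - y_i(t_j,\theta)}{\sigma_{ij}(\theta)}\right)^{\!2} \right],$$

implemented by `nll_from_residuals()`. The double sum over observables and
time points is flattened to a single residual index throughout the package:
none of the algorithms need the two-dimensional structure. With
parameter-independent $\sigma$ the problem is a weighted least-squares
problem; with $\sigma(\theta)$ it is not, which is exactly the case the GNe
correction (below) addresses.

The package does not integrate differential equations. A user supplies an
evaluation callback through `tr_objective()` returning the objective value,
its gradient, and — for least-squares schemes — the standardized residual
vector and its Jacobian, plus optional noise values and noise gradients.
An `ok = FALSE` return (or a thrown error, or non-finite values) signals an
evaluation failure; for ODE models this is typically an integration
failure, and the optimizer treats it as a failed trial rather than an
error. The factor $\tfrac12$ in $J$ is part of the contract: success
thresholds such as $\tau = 2$ are calibrated to this scaling.

## The trust-region iteration

`tr_minimize()` iterates the classical loop: at the current iterate build
the quadratic model $m_k(p) = f_k + g_k^T p + \tfrac12 p^T B_k p$, solve
the subproblem $\min_{\|p\| \le \Delta_k} m_k(p)$, evaluate the trial
point, and compare the actual decrease $\Delta J$ with the predicted
decrease $-m_k(p)$ via the ratio $\rho_k$. Steps are accepted when
$\rho_k > \mu$ with $\mu = 0$; when the model predicts an increase
($-m_k(p) \le 0$, which can happen through the bound-handling augmentation
described below) $\rho_k$ is set to $0$, preventing spurious acceptance
when both quantities are negative.

The radius rules are the interior-reflective variant implemented in
`update_radius()`:

* $\rho_k > 0.75$ and $\|p\| > 0.9\,\Delta_k$ (the model is accurate and
  the solution presses against the region): $\Delta_{k+1} = 2\Delta_k$;
* $\rho_k < 0.25$, or the trial evaluation failed:
  $\Delta_{k+1} = \min(\Delta_k, \|p\|)/4$;
* otherwise the radius is unchanged. The changed/unchanged flag is
  recorded per iteration; a long run of unchanged radii is the signal the
  hybrid scheme listens to.

Exactly one objective-and-gradient evaluation is spent per iteration (the
trial evaluation is reused as the next iterate's gradient on acceptance),
so the gradient-evaluation count equals the iteration count — the
bookkeeping that makes $\nu = 1/n_\text{grad}$ interpretable as a
convergence rate.

**Numerical choices.** The initial radius is $\Delta_0 = 1$ in scaled
coordinates (configurable). Convergence is declared when the norm of the
*proposed* step falls below `step_tol` ($10^{-6}$ by default), checked
every iteration rather than only on accepted steps: at a converged iterate
the predicted decrease is $\approx 0$, so the ratio test would never accept
again and an accepted-steps-only rule would spin until the iteration cap
($10^5$ by default). A radius below $10^{-16}$ terminates with status
`"failure"` to guard against pathological objectives. The strictness of
the $\rho$ inequalities (strict `>` and `<`) is a documented choice; the
middle band never changes the radius.

## Hessian approximation schemes

All schemes produce the matrix $B_k$ of the quadratic model; the gradient
is always exact (supplied by the user). Least-squares schemes consume the
residual Jacobian $J_r$ with rows $\nabla r_k^T$.

* **GN** — $B = J_r^T J_r$, the outer-product sum over residual
  gradients. Exact for affine standardized residuals (this fixes the
  scaling convention: `gauss_newton()` is the exact Hessian of
  $\tfrac12\|r\|^2$ in the affine limit), positive semi-definite, blind to
  residual curvature. Its error against the true Hessian is
  $\sum_k r_k \nabla^2 r_k$, which does not vanish for non-zero-residual
  problems.
* **GNe** — GN plus, per residual, the error-residual correction
  $\nabla\sigma \nabla\sigma^T / \big(\sigma^2 (2\log\sigma + C)\big)$,
  which restores a least-squares structure when $\sigma$ depends on
  $\theta$. The offset $C$ (default 50) must satisfy
  $2\log\sigma + C > 0$ for every residual; violations raise an error
  naming the offending residual. As $C \to \infty$ the correction vanishes
  and GNe reduces to GN.
* **BFGS / SR1** — iterative secant updates from an identity
  initialization. BFGS rejects updates violating the curvature condition
  $z^Ts > \varepsilon_\text{mach}\,\|z\|\|s\|$ (preserving positive
  semi-definiteness); SR1 skips when
  $|(z - Ms)^Ts| \le 10^{-8}\|s\|\|z - Ms\|$ and can go indefinite, which
  is the point — it can represent negative curvature. Update pairs
  $(s, z)$ are formed from accepted steps only; rejected proposals never
  feed the recursions.
* **SSM / TSSM** — structured secant methods adding an iteratively
  BFGS-updated matrix $A_k$ (initialized to zero) to GNe to model the
  residual-curvature term, using the structured secant vector
  $z^\# = (J_r(\theta_{k+1}) - J_r(\theta_k))^T r(\theta_{k+1})$. TSSM
  scales $A_k$ by the residual norm and the update to $A_k$ by its
  inverse, mimicking the product structure of the curvature term. The
  TSSM recursion as commonly printed is typographically ambiguous; the
  implementation uses $z^\dagger = B^{(GNe)}s + z^\#\,\|r_{k+1}\|/\|r_k\|$
  with the inner update evaluated at $B^{(GNe)} + \|r_{k+1}\|A_k$ and the
  resulting rank-two term divided by $\|r_{k+1}\|$ — the reading
  consistent with the stated scaling intent. Both inner updates apply the
  BFGS curvature skip; whether the original formulations do is unstated,
  and the skip is adopted for numerical safety. Neither scheme preserves
  positive semi-definiteness (the pointwise GNe part is replaced fresh
  every iteration while $A_k$ accumulates unconstrained).
* **FX** (Fletcher–Xu) — per iteration, if the relative residual-norm
  decrease $(\|r_k\| - \|r_{k+1}\|)/\|r_k\|$ falls below
  $\epsilon_{FX} = 0.2$ (a non-zero-residual signature), BFGS-update the
  carried matrix; otherwise restart from fresh GNe. Always positive
  semi-definite.
* **GNSBFGS** — the structured analogue with a switch: when the curvature
  estimate $z^{\diamond T}s / s^Ts$ (with
  $z^\diamond = z^\#\|r_{k+1}\|/\|r_k\|$) exceeds
  $\epsilon_{GNSBFGS} = 10^{-6}$, use $B^{(GNe)} + A_{k+1}$ with $A$
  BFGS-updated by $z^\diamond$; otherwise fall back to
  $B^{(GNe)} + \|r_{k+1}\| I$ with $A$ untouched. $A$ is initialized to
  the identity so both branches are positive semi-definite.
* **HYBRID** — the switching scheme: use pointwise GN while silently
  BFGS-updating a shadow matrix on every accepted step; after `n_hybrid`
  *consecutive* iterations in which the trust-region radius was not
  updated (any radius change resets the counter), switch permanently to
  the shadow BFGS matrix. The rationale: GN's basin-finding behavior is
  valuable early, while its curvature error throttles local convergence
  late — the radius stall is the observable symptom of that throttling.

The structured and hybrid schemes build on GNe with $C = 50$ whenever
noise gradients are available, since they require a least-squares
structure; with constant noise GNe and GN coincide.

## Solving the subproblem

Two solvers are provided. `solve_tr_nd()` solves the subproblem *exactly*
by eigendecomposition: an interior Newton point when admissible, otherwise
safeguarded root-finding on the secular equation
$\|p(\lambda)\| = \Delta$ for the Lagrange multiplier
$\lambda \ge \max(0, -\lambda_{\min})$, with the hard case (gradient
orthogonal to the bottom eigenspace) handled by adding a component along
the most negative eigenvector to reach the boundary. Dense
eigendecomposition is acceptable for the target problem sizes (tens to a
few hundred parameters), where objective evaluations dominate runtime.

`solve_tr_2d()` restricts the model to the plane spanned by the gradient
and the Newton direction, computed as the minimum-norm least-squares
solution $B^+(-g)$ via the Moore–Penrose pseudoinverse, so singular
approximations are handled without regularization. When $B$ has a
negative eigenvalue beyond numerical noise
($\lambda_{\min} < -\varepsilon\,|\lambda_{\max}|$, $\varepsilon$ the
machine spacing at 1), the Newton direction is replaced by the
most-negative eigenvector — the direction of strongest negative
curvature. When the two basis vectors are parallel the plane degenerates
and the model is minimized exactly on the line. The restricted
$2\times 2$ problem is solved with the exact solver, so the 2D solution
is never better than ND and never worse than the Cauchy point.

## Bounds: scaling, reflection, truncation

Bound handling follows the interior-affine-scaling construction. The
distance-to-bound vector $v(\theta)$ selects, per coordinate, the distance
to the bound the gradient points toward ($\theta_i - u_i$ or
$\theta_i - l_i$), or $\mp 1$ for infinite bounds. With
$D = \mathrm{diag}(|v|^{1/2})$ the model is transformed to
$\hat B = D B D + \mathrm{diag}(g)\,\partial|v|/\partial\theta$ and
$\hat g = D g$. The derivative factor is $\pm 1$ on the finite-bound
branches with the sign of $\partial|v_i|/\partial\theta_i$, which makes
the diagonal augmentation $g_i \cdot dv_i$ nonnegative in every admissible
state — the transformation can only regularize the subproblem. (Taking the
derivative of $v$ itself rather than $|v|$ would flip the sign on the
upper-bound branch and destroy this property; the package uses
$\partial|v|$.)

The subproblem is solved in scaled coordinates and the step mapped back
through $D$ before boundary geometry is applied in original coordinates.
Candidate scoring uses the equivalent original-coordinate model
$B_\text{eff} = B + \mathrm{diag}(g\,dv/|v|)$, so the predicted decrease
always includes the augmentation term — this is also the predicted
decrease used in $\rho_k$, which is how the "augmented prediction" is
realized here.

If the mapped proposal stays interior it is used as-is. Otherwise three
stepback candidates compete on model value (`select_step()`, ties broken
toward the larger step, then reflection before truncation before Cauchy):

1. **Reflection** — walk the piecewise-linear path obtained by folding
   the proposal at each bound it crosses, total arc length $\|p\|$,
   minimizing the model analytically on each segment and stopping at the
   first segment whose minimizer is interior to it (the first local
   minimum along the path). `max_reflections = 1` reproduces the
   single-reflection variant used by older implementations; the multi
   variant explores a superset of the single variant's path, so its model
   value is never worse. A safety cap of $100\,n_\theta$ reflections
   guards against degenerate cycling.
2. **Truncation** — the proposal scaled by the largest feasible
   $\alpha \in [0, 1]$.
3. **Constrained Cauchy** — exact minimization along the scaled
   steepest-descent direction, truncated at the trust region and the box.

Every candidate is pulled strictly inside the box by a relative backoff of
$10^{-10}$ (of the box width per coordinate): the method is an interior
method and no iterate may touch a bound, where the scaling vector would
vanish.

## Diagnostics and multistart metrics

Each iteration appends a trace row: objective value, gradient norm,
radius, ratio, acceptance, step kind, whether the radius and the Hessian
approximation were updated, whether the transformed Hessian was
numerically singular (condition number above
$1/\varepsilon_\text{mach}$), whether the approximation had a negative
eigenvalue beyond noise, evaluation failures, boundary engagement, and the
hybrid switch state. `trace_statistics()` reduces a trace to per-run event
fractions; these are the quantities whose correlation with performance
motivated the hybrid scheme in the first place. Computing the two
decompositions per iteration is cheap at the target sizes and can be
disabled with `diagnostics = FALSE`.

`tr_multistart()` runs many independent minimizations from uniform start
points and reports, per success threshold $\tau$: the success count
$\gamma$ (runs within $\tau$ of the best final value; failed runs are
excluded from the minimum but keep their evaluation budget in the
denominator), the convergence rate $\nu = 1/n_\text{grad}$, and the
performance $\phi = \gamma\,\nu$, computed literally as that product so
the identity is exact in floating point. The default $\tau = 2$
corresponds to the non-rejection limit of the Akaike information
criterion on the $\tfrac12$-scaled negative log-likelihood; $\tau = 0.05$
and $\tau = 5$ are conventional alternatives, and $\gamma$ is monotone in
$\tau$ by construction. The overlap of successful start sets between two
settings is summarized by the Jaccard index
(`startpoint_overlap()`); the score of two empty sets is 0 by convention.

## Synthetic study problems

The package tests itself on generated problems; no external data is
involved anywhere.

`make_nls_problem()` builds nonlinear least-squares problems with a
*constructed* optimum: an affine map $A$ (singular values chosen so the
GN eigenvalues at the optimum are log-spaced over a requested number of
decades — the "sloppiness" dial) composed with a monotone coordinate-wise
sine warp, a residual offset $c$ in the null space of $A^T$ (so the
gradient vanishes at $\theta^*$ while $\|r(\theta^*)\|$ is exactly the
requested norm), and a quadratic residual term aligned with $c$ that
leaves the optimum, gradient, and GN matrix untouched but contributes
$\text{curvature} \cdot S$ (random PSD $S$, unit spectral norm) to the
true Hessian at the optimum. That last term matters: without it, any
coordinate-wise-warp construction has *zero* residual curvature at the
optimum — the correction term is $\mathrm{diag}(w''\,(A^Tc)) = 0$
precisely because $A^Tc = 0$ — and GN would be exact at the optimum, which
is the opposite of the non-zero-residual regime the fixture exists to
emulate.

`conversion_model()` is a closed-form two-species reversible conversion
$X_1 \rightleftharpoons X_2$ under mass-action kinetics, observed as
$y = x_2$, with analytic sensitivities, rates estimated on the log10
scale, and optionally the noise scale as a free parameter (activating the
GNe correction). Defaults — $k_1 = 2$, $k_2 = 0.5$, $x_0 = (1, 0)$,
16 time points on $[0, 5]$, $\sigma = 0.02$ — were chosen once as a
plausible desk-scale analogue of a fast reversible reaction observed over
a few relaxation times with a few percent measurement noise.

**Desk-scale study conditions.** The multistart experiments run by the
test suite and by `scripts/acceptance.R` use: a zero-residual recovery
problem (4 parameters, 8 residuals, 2-decade spectrum), a sloppy
non-zero-residual problem (5 parameters, 12 residuals, residual norm 2,
6-decade spectrum), 100 starts, an iteration cap of 1000, and
`n_hybrid = 5`. The stall window deserves a note: published full-scale
studies with iteration caps of $10^5$ favor `n_hybrid` around 50, but the
window should be small relative to typical run lengths, and desk-scale
runs converge in tens to a few hundred iterations; 5 scales that choice
accordingly (and remains the package default only for these experiments —
`tr_options()` defaults to 50).

**What passing these tests does and does not show.** The fixtures have
smooth analytic residuals, exactly known optima, modest dimension, and
Gaussian noise by construction. They exercise every code branch
(indefinite and singular models, the hard case, boundary folding,
evaluation failures, parameter-dependent noise) and they reproduce the
*mechanism* behind the hybrid scheme — GN stalling on sloppy
non-zero-residual problems, BFGS converging fast once in a basin. They do
not demonstrate performance on stiff ODE systems with integration-failure
regions, non-identifiable ridges of real posteriors, or problems with
hundreds of parameters; conclusions at that scale require real benchmark
corpora and a simulator, both outside this package's scope.

## Known limitations

* The optimizer expects user-supplied exact gradients; there is no
  finite-difference fallback (deliberately: inaccurate gradients are a
  known cause of premature termination, and silently providing them would
  mask that).
* No line-search globalization, no Wolfe-condition machinery, and no
  iterative (Steihaug-CG-style) subproblem solver; dense
  eigendecomposition bounds practical problem size to roughly $10^3$
  parameters.
* Multistart runs execute sequentially; results are start-index-ordered
  and bit-reproducible for a given seed, which is the property the
  package prioritizes over wall-clock parallelism.
* Trace export offers CSV and RDS containers; no HDF5 backend.
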