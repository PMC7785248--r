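---
title: "Confidence-interval endpoints by constrained optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-interval endpoints by constrained optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cico)
```

## The problem

A kinetic model fitted to noisy, incomplete data rarely pins down all of its
parameters. *Practical identifiability* analysis asks which parameters the
data actually constrain, and by how much. The standard likelihood-based answer
uses the profile likelihood: for the parameter of interest $\theta_i$,

$$ l_{PL}(\theta_i) = \min_{\theta_{j \ne i}} l(\boldsymbol\theta), $$

where $l(\boldsymbol\theta) = -2\log\Lambda(\boldsymbol\theta)$ is the
negative log-likelihood (for additive Gaussian error with known variance, the
weighted sum of squared residuals). The confidence interval at level $\alpha$
is the sub-level set

$$ CI_{\alpha,\theta_i} = \{\theta_i : l_{PL}(\theta_i) - l(\hat{\boldsymbol\theta})
   \le \Delta_\alpha\}, $$

with $\Delta_\alpha$ a $\chi^2$ quantile (likelihood-ratio test). A parameter
is practically non-identifiable when this set extends to infinity on either
side even though the likelihood has a unique minimum.

Computing $l_{PL}$ pointwise is expensive: each grid point is a full nuisance
re-optimization, and non-identifiable directions — where the profile is nearly
flat — are the *most* expensive to explore. Yet the analysis only needs the
two *endpoints* of the interval, not the whole profile.

## Endpoints as constrained optima

The endpoints are the extreme feasible values of $\theta_i$ within the
confidence region $\{\boldsymbol\theta : l(\boldsymbol\theta) \le
l^*_\alpha\}$, where $l^*_\alpha = l(\hat{\boldsymbol\theta}) +
\Delta_\alpha$. So each endpoint solves a constrained program:

$$ \theta_i^{L} = \arg\min\ \theta_i
   \quad\text{s.t.}\quad l(\boldsymbol\theta) - l^*_\alpha \le 0,
   \qquad
   \theta_i^{U} = \arg\min\ (-\theta_i)
   \quad\text{s.t.}\quad l(\boldsymbol\theta) - l^*_\alpha \le 0. $$

The first-order (KKT) conditions of these programs are exactly the endpoint
equations of the profile-likelihood interval, with the Lagrange multiplier
playing the role of the inverse profile slope. Geometrically, the search looks
for the hyperplane $\theta_i = \text{const}$ tangent to the confidence region.

`find_endpoint()` solves each program with an **augmented Lagrangian**: the
inequality constraint $g(\boldsymbol\theta) = l(\boldsymbol\theta) -
l^*_\alpha$ is folded into the objective through

$$ \psi(g; \mu, \rho) = \begin{cases}
  \mu g + \tfrac{\rho}{2} g^2, & g \ge -\mu/\rho, \\[2pt]
  -\mu^2 / (2\rho), & \text{otherwise},
\end{cases} $$

and the resulting unconstrained problem is handed to a local optimizer. The
outer loop then updates $\mu \leftarrow \max(0, \mu + \rho\, g)$ and grows
$\rho$ tenfold whenever the constraint violation fails to shrink by a factor
of 4 (capped at $10^{12}$) — the classic multiplier schedule. $\mu$ starts at
0 and $\rho$ at 1. Intermediate iterates are *not* required to lie on the
profile path, which is where the evaluation-count savings come from,
especially for flat (non-identifiable) directions where the penalty term
simply never activates.

## Scan bounds and the two termination certificates

Declaring a parameter non-identifiable in the strict sense would require
exploring all of $\mathbb{R}$. Instead the search is confined to declared
*scan bounds* $(\theta_i^{BL}, \theta_i^{BU})$ — biologically or numerically
plausible ranges — and terminates with one of two certificates:

* **`BORDER_FOUND_BY_SCAN_TOL`** — the endpoint estimate moved less than
  `scan_tol` between successive outer iterations while the constraint is
  active within `loss_tol`. The endpoint lies on the confidence-region
  boundary, strictly inside the scan bounds.
* **`SCAN_BOUNDS_REACHED`** — a point with $l < l^*_\alpha -$ `loss_tol` was
  certified with $\theta_i$ at the scan bound: the confidence region leaks out
  of the declared range and the parameter is *practically non-identifiable
  within the bounds* in that direction. No endpoint value is reported.

A parameter is *identifiable within the bounds* exactly when both directions
return the first certificate, i.e. $[\theta_i^L, \theta_i^U] \subseteq
(\theta_i^{BL}, \theta_i^{BU})$. A third status, `MAX_ITER_STOP`, flags an
exhausted evaluation budget — no certificate at all.

The scan bound is imposed as a hard box face on $\theta_i$ for the inner
optimizer, so non-identifiability is certified constructively by a feasible
point *at* the face, never inferred from divergence heuristics. The outer
stopping rule (estimate stall + constraint activity) is this package's own
formalization; its correctness is validated against the stepwise-profile
oracle in the test suite rather than assumed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha`, `df` | 0.95, 1 | confidence level and $\chi^2$ degrees of freedom for $\Delta_\alpha$ |
| `loss_crit` | — | explicit threshold $l^*_\alpha$; overrides `alpha`/`df` |
| `scan_bounds` | `(1e-9, 1e9)` | feasible range of the scanned parameter, natural scale (`(1e-9, 1-1e-9)` for logit); pass explicit bounds for sign-indefinite parameters |
| `scales` | `"direct"` | per-parameter search scale: `direct`, `log` (base 10), `logit` |
| `scan_tol` | `1e-3` | absolute endpoint tolerance, in the search scale |
| `loss_tol` | `1e-3 * delta` | constraint-activity tolerance at a certified endpoint |
| `max_evals` | `1e5` | loss-evaluation budget per endpoint |
| `local_alg` | `"nelder-mead"` | inner optimizer (`"nlminb"` as a quasi-Newton alternative) |

The `df = 1` default gives pointwise intervals for one parameter at a time —
the usual convention in identifiability work; set `df` to the parameter count
for simultaneous (projection) intervals. Tolerances are interpreted in the
search scale so that one `scan_tol` means the same thing for a rate constant
spanning decades (log scale) and for a fraction (logit scale). `loss_tol`
scales with $\Delta_\alpha$ because constraint activity is only meaningful
relative to the height of the threshold above the minimum.

## Numerical choices

* **Failure sentinel.** Loss evaluations that error or return non-finite
  values are reported as $+\infty$ (and counted). Derivative-free simplex
  steps simply retreat from such regions, which is why the default inner
  optimizer is Nelder-Mead: stiff-ODE likelihoods routinely fail to integrate
  at extreme parameter values, and gradient-based methods would abort there.
* **Box handling.** The inner optimizer runs unconstrained; every trial point
  is clamped to the box before evaluation, plus a small quadratic pull-back
  term `100 * ||x - clamp(x)||^2` that steers the simplex back inside without
  moving the constrained optimum.
* **One-parameter problems** use golden-section search over the box instead of
  a simplex.
* **Degenerate profile slope.** If the endpoint estimate stalls while the
  constraint is still inactive (the rare $\partial l / \partial\theta_i = 0$
  boundary case), the search warns and keeps iterating under the penalty
  schedule instead of special-casing; lowering the tolerances is the
  documented remedy.
* **Multimodality.** The first certified endpoint wins; no global search is
  attempted. Like any local method, the search inherits the local optimizer's
  basin — restart from different feasible points to probe multimodal
  likelihoods.
* **Determinism.** Nelder-Mead and the multiplier schedule are deterministic
  given `theta_init`, so identical inputs reproduce identical reports.

## The stepwise-profile oracle

`profile_loss()` implements the classic alternative: fix $\theta_i$ on a
grid, re-optimize all nuisance parameters at each point (warm-started,
sweeping outward from the start in both directions), then interpolate the
threshold crossing with `profile_crossing()`. It is deliberately simple and
costly — it exists as an *independent check*, not as the recommended path.
The test suite requires constrained-optimization endpoints and interpolated
profile crossings to agree within `max(scan_tol, grid spacing)` on every
bundled fixture, and the typical observed disagreement is around $10^{-5}$
with roughly 100× fewer evaluations for the constrained search than a
comparably accurate profile.

## What the synthetic generator does and does not emulate

`make_linear_dataset()` and `make_biexponential_dataset()` draw observations
$\hat y_j = g(t_j, \boldsymbol\theta) + \varepsilon_j$, $\varepsilon_j \sim
N(0, \sigma_j^2)$ with *known* $\sigma_j$, matching the weighted
sum-of-squares likelihood of `wssr_loss()` exactly. They are closed-form
observables, chosen so the whole test suite runs in seconds without an ODE
solver:

* the linear model is the well-conditioned identifiable case; its profile
  intervals coincide with the exact normal-theory intervals, so a
  Monte-Carlo experiment (200 replicates of 11 time points, $\sigma = 1$,
  slope 2, intercept 1 — sizes chosen to keep the whole experiment near
  realistic per-dataset information content) must recover 95% coverage up to
  Monte-Carlo error, and does;
* the biexponential model $a_1 e^{-k_1 t} + a_2 e^{-k_2 t}$ with $k_1 = k_2$
  has an exact amplitude-exchange symmetry: only $a_1 + a_2$ and the common
  rate are recoverable, so individual amplitudes hit the scan bounds — a
  minimal, solver-free analogue of the data-starved compartment models where
  non-identifiability actually bites.

What they do *not* emulate: estimated (rather than known) noise variance,
non-Gaussian or multiplicative error, correlated residuals, ODE-solver
failure regions, and the cost profile of real ODE likelihoods. Passing tests
therefore demonstrate the correctness of the endpoint search on smooth,
cheap, exactly-specified likelihoods; they do not certify behavior under
solver noise, which users of stiff models should probe with their own loss
functions (the $+\infty$ sentinel is designed for exactly that).

## Validation problem sizes

The bundled validation uses two-parameter toys (analytic endpoints), a
four-parameter biexponential (oracle comparison on a 161-point profile grid),
and the 200-replicate coverage study described above. These sizes were chosen
so each check isolates one property at desk scale; the algorithm itself has
no dimension-specific logic and runs unchanged on larger models supplied as
user loss functions.

## Known limitations

* Confidence *regions* and prediction bands are out of scope; only
  per-parameter intervals are computed.
* Integration-based profiling (Hessian or adjoint-based) is not implemented;
  the stepwise profiler here is an oracle, not a performance baseline.
* The endpoint search is local: on multimodal likelihoods, disconnected
  islands of the confidence region beyond a ridge can be missed.
* Scan bounds truncated by `theta_bounds` are reported as scan-bound hits;
  the distinction between "user box" and "scan range" collapses at the face.
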