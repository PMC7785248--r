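# cico — profile-likelihood confidence intervals by constrained optimization

Practical identifiability analysis asks how precisely a model's parameters can
be recovered from the available data. For a negative log-likelihood
`l(θ)` minimized at `θ̂`, the standard likelihood-based answer for one
parameter `θᵢ` is the profile-likelihood confidence interval

    CI_α(θᵢ) = { θᵢ : l_PL(θᵢ) − l(θ̂) ≤ Δ_α },
    l_PL(θᵢ) = min over θ_{j≠i} of l(θ),

with `Δ_α` a chi-square quantile (likelihood-ratio test). Computing `l_PL`
point by point is expensive — every grid point is a full nuisance
re-optimization, and flat (non-identifiable) profiles are the worst case.

This package obtains each interval **endpoint directly** as the solution of a
constrained program

    minimize ±θᵢ   subject to   l(θ) ≤ l*_α = l(θ̂) + Δ_α,

solved with an augmented Lagrangian around a derivative-free local optimizer.
Intermediate points need not lie on the profile path, which cuts the number
of likelihood evaluations dramatically, and declared *scan bounds* give a
formal termination certificate for practically non-identifiable parameters
(`SCAN_BOUNDS_REACHED`) instead of heuristics. It is aimed at systems-biology
and QSP modelers, but any scalar loss over a parameter vector works — the
likelihood enters only through function evaluations, so ODE-solver failures
are tolerated (they are absorbed as `+Inf` and stepped around).

## Worked example

The loss below has its minimum `l(3, 2) = 5`; with the threshold set to 9 the
confidence region is the ellipse `(θ₁−3)² + (θ₁−θ₂−1)² ≤ 4`:

```r
library(cico)

quad <- function(theta) 5 + (theta[1] - 3)^2 + (theta[1] - theta[2] - 1)^2
fit <- cico(quad, theta_init = c(3, 2), loss_crit = 9, scan_bounds = c(-50, 50))
fit
#> Confidence intervals by constrained optimization
#>   loss_crit = 9
#>  parameter estimate     lower   upper             status_lower
#>          1        3  0.999990 5.00001 BORDER_FOUND_BY_SCAN_TOL
#>          2        2 -0.828439 4.82844 BORDER_FOUND_BY_SCAN_TOL
#>              status_upper identifiable loss_calls
#>  BORDER_FOUND_BY_SCAN_TOL         TRUE        584
#>  BORDER_FOUND_BY_SCAN_TOL         TRUE        608
```

Both parameters are practically identifiable: every endpoint carries the
`BORDER_FOUND_BY_SCAN_TOL` certificate, meaning the search converged (within
`scan_tol = 1e-3`) to a point on the confidence-region boundary. The values
match the analytic optima `[1, 5]` and `[2 − 2√2, 2 + 2√2] ≈ [−0.8284,
4.8284]`, each endpoint costing a few hundred loss evaluations. Compare a
non-identifiable case — the flat Rosenbrock valley, scanned on `(−5, 5)`:

```r
summary(cico(rosenbrock, c(1, 1), parm = 1, loss_crit = 200, scan_bounds = c(-5, 5)))
#> Practical identifiability summary
#>   loss_crit = 200, total loss calls = 908
#>  parameter estimate lower upper        status_lower        status_upper
#>          1        1    NA    NA SCAN_BOUNDS_REACHED SCAN_BOUNDS_REACHED
#>  identifiable loss_calls
#>         FALSE        908
```

Here the likelihood stays below the threshold all the way to both scan
bounds: no endpoint exists inside the declared range, and the bound hit is
certified by an explicit feasible point at the box face.

Useful companions: `confint(fit)` / `coef(fit)` for the endpoint matrix,
`plot(fit, parm = 1)` for a profile-plus-endpoints figure,
`find_interval()` / `find_endpoint()` for single searches with full control
(scales `direct`/`log`/`logit`, per-parameter boxes, budgets), and
`profile_loss()` / `profile_crossing()` for the brute-force stepwise profile
used as an independent cross-check. Real-likelihood workflows start from
`fit_mle()`, or from `wssr_loss()` +
`make_linear_dataset()`/`make_biexponential_dataset()` for synthetic
Gaussian-noise data. A thin command-line driver ships in `inst/cli/cico`
(see `?cico_cli`).

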