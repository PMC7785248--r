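#' Augmented-Lagrangian objective for one endpoint search
#'
#' The lower (upper) endpoint of a likelihood-based confidence interval for
#' parameter `i` is the solution of the constrained problem: minimize
#' `f(theta) = +theta_i` (resp. `-theta_i`) subject to
#' `g(theta) = l(theta) - loss_crit <= 0`. The constraint is folded into the
#' objective with the standard inequality-constraint augmented-Lagrangian term
#' `psi(g, mu, rho)`:
#'
#' `psi = mu * g + (rho / 2) * g^2` when `g >= -mu / rho`, else
#' `psi = -mu^2 / (2 * rho)` (and `psi = mu * g` in the `rho = 0` limit).
#'
#' This function evaluates `f(theta) + psi(g(theta), mu, rho)`; it is exposed
#' mainly for testing and for plugging in custom outer loops.
#'
#' @param theta numeric parameter vector (natural scale).
#' @param mu multiplier, `>= 0`.
#' @param rho penalty weight, `>= 0`.
#' @param loss a loss function or `"counted_loss"` evaluator.
#' @param index which parameter is being profiled.
#' @param direction `"lower"` or `"upper"`.
#' @param loss_crit the critical loss value (threshold).
#' @return scalar value of the augmented objective (`+Inf` if the loss
#'   evaluation fails).
#' @examples
#' q <- function(th) 5 + (th[1] - 3)^2 + (th[1] - th[2] - 1)^2
#' # point exactly on the constraint boundary: psi = mu * g = 0
#' augmented_objective(c(1, 0), mu = 1, rho = 0, loss = q,
#'                     index = 1, direction = "lower", loss_crit = 9)
#' @export
augmented_objective <- function(theta, mu, rho, loss, index,
                                direction = c("lower", "upper"), loss_crit) {
  direction <- match.arg(direction)
  ev <- counted_loss(loss)
  sgn <- if (direction == "lower") 1 else -1
  g <- ev(theta) - loss_crit
  sgn * theta[index] + al_penalty(g, mu, rho)
}

# psi(g, mu, rho): augmented-Lagrangian term for one inequality constraint
al_penalty <- function(g, mu, rho) {
  if (!is.finite(g)) return(Inf)
  if (rho <= 0) return(mu * g)
  if (g >= -mu / rho) mu * g + 0.5 * rho * g^2 else -mu^2 / (2 * rho)
}

# termination check shared by the outer loop (internal).
# best_feasible: list(x, loss) in search scale or NULL; faces: c(lo_i, hi_i).
certify_termination <- function(best_feasible, endpoint_est, prev_endpoint,
                                loss_at_est, direction, faces,
                                loss_crit, scan_tol, loss_tol) {
  if (!is.null(best_feasible) &&
      is.finite(best_feasible$loss) &&
      best_feasible$loss < loss_crit - loss_tol) {
    at_face <- if (direction == "lower")
      best_feasible$x_i <= faces[1] + scan_tol
    else
      best_feasible$x_i >= faces[2] - scan_tol
    if (at_face) return("SCAN_BOUNDS_REACHED")
  }
  if (!is.na(prev_endpoint) &&
      abs(endpoint_est - prev_endpoint) < scan_tol &&
      is.finite(loss_at_est) &&
      abs(loss_at_est - loss_crit) <= loss_tol) {
    return("BORDER_FOUND_BY_SCAN_TOL")
  }
  "CONTINUE"
}

#' Find one confidence-interval endpoint by constrained optimization
#'
#' Searches for the lower or upper endpoint of the profile-likelihood
#' confidence interval of `theta_init[index]` as the solution of
#' "minimize `+-theta_i` subject to `l(theta) <= loss_crit`", using an outer
#' augmented-Lagrangian loop (multiplier update and penalty growth) around a
#' derivative-free local optimizer, instead of tracing the likelihood profile.
#'
#' Termination is governed by two formal criteria:
#' \describe{
#'   \item{`BORDER_FOUND_BY_SCAN_TOL`}{the endpoint estimate moved less than
#'     `scan_tol` between successive outer iterations while the constraint is
#'     active, `|l(theta*) - loss_crit| <= loss_tol`: the endpoint lies on the
#'     confidence-region boundary.}
#'   \item{`SCAN_BOUNDS_REACHED`}{a point with `l < loss_crit - loss_tol` was
#'     certified with `theta_i` at the scan bound: the confidence region
#'     extends past the declared feasible range, so the parameter is
#'     practically non-identifiable within the bounds in this direction. No
#'     endpoint is reported.}
#'   \item{`MAX_ITER_STOP`}{the evaluation budget was exhausted before either
#'     certificate was obtained.}
#' }
#'
#' @param loss the negative log-likelihood: a function of the full parameter
#'   vector, or a [counted_loss()] evaluator.
#' @param theta_init numeric start vector, typically (but not necessarily) the
#'   maximum-likelihood estimate; must be feasible, `loss(theta_init) <
#'   loss_crit`.
#' @param index integer, which parameter's endpoint to search.
#' @param direction `"lower"` or `"upper"`.
#' @param loss_crit critical loss value; if `NULL` it is computed as
#'   `loss(theta_init) + qchisq(alpha, df)`.
#' @param alpha,df confidence level and chi-square degrees of freedom used when
#'   `loss_crit` is not given (see [loss_threshold()]).
#' @param scan_bounds length-2 numeric, the feasible range for parameter
#'   `index` on the natural scale. Default `c(1e-9, 1e9)` (`c(1e-9, 1 - 1e-9)`
#'   for a logit-scaled parameter); pass explicit bounds for parameters that
#'   may be negative. Converted to the search scale internally.
#' @param theta_bounds optional `m x 2` matrix of boxes for all parameters on
#'   the natural scale; default is `(-1e9, 1e9)` per parameter in the search
#'   scale.
#' @param scales per-parameter search scale(s), see [to_search_scale()].
#' @param scan_tol absolute endpoint tolerance, in the search scale.
#' @param loss_tol tolerance on `|l(theta*) - loss_crit|` at a certified
#'   endpoint; default `1e-3 * (loss_crit - l(theta_init))`.
#' @param max_evals budget of loss evaluations for this search.
#' @param local_alg inner unconstrained optimizer: `"nelder-mead"` (default,
#'   derivative-free) or `"nlminb"` (quasi-Newton with numerical gradients).
#' @param record_trace keep all visited points (retrievable via the returned
#'   `trace`).
#' @param max_outer maximum number of outer augmented-Lagrangian iterations.
#' @param verbose print one line per outer iteration.
#' @return an object of class `"cico_endpoint"`: list with `endpoint` (natural
#'   scale, `NA` unless the border was found), `status`, `loss_calls`,
#'   `argument` (full parameter vector at the endpoint, natural scale, or
#'   `NULL`), `loss` (loss at `argument`), `loss_crit`, `direction`, `index`,
#'   `trace` (data frame or `NULL`) and `outer_iterations`.
#' @examples
#' q <- function(th) 5 + (th[1] - 3)^2 + (th[1] - th[2] - 1)^2
#' find_endpoint(q, c(3, 2), index = 1, direction = "upper", loss_crit = 9,
#'               scan_bounds = c(-50, 50))$endpoint  # ~5
#' @seealso [find_interval()], [cico()], [profile_loss()]
#' @export
find_endpoint <- function(loss, theta_init, index,
                          direction = c("lower", "upper"),
                          loss_crit = NULL, alpha = 0.95, df = 1,
                          scan_bounds = NULL, theta_bounds = NULL,
                          scales = "direct",
                          scan_tol = 1e-3, loss_tol = NULL,
                          max_evals = 100000L,
                          local_alg = c("nelder-mead", "nlminb"),
                          record_trace = FALSE, max_outer = 100L,
                          verbose = FALSE) {
  direction <- match.arg(direction)
  local_alg <- match.arg(local_alg)
  m <- length(theta_init)
  if (!is.numeric(theta_init) || m < 1L || anyNA(theta_init))
    stop("'theta_init' must be a numeric vector without NAs", call. = FALSE)
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index > m)
    stop("'index' must be a single parameter index in 1..", m, call. = FALSE)
  index <- as.integer(index)
  scales <- check_scales(scales, m)
  if (!is.numeric(scan_tol) || scan_tol <= 0) stop("'scan_tol' must be > 0", call. = FALSE)
  if (max_evals < 1) stop("'max_evals' must be >= 1", call. = FALSE)

  ev <- counted_loss(loss, record_trace = record_trace)
  calls0 <- loss_calls(ev)
  trace0 <- if (record_trace) nrow(loss_trace(ev)) else NA_integer_

  l0 <- ev(theta_init)
  thr <- loss_threshold(l0, alpha = alpha, df = df, loss_crit = loss_crit)
  crit <- thr$loss_crit
  if (!(l0 < crit))
    stop(sprintf(paste0("the start is infeasible: loss(theta_init) = %g >= loss_crit = %g; ",
                        "refit the model or raise loss_crit"), l0, crit),
         call. = FALSE)
  if (is.null(loss_tol)) loss_tol <- 1e-3 * thr$delta
  if (!is.numeric(loss_tol) || loss_tol <= 0) stop("'loss_tol' must be > 0", call. = FALSE)

  # --- search-scale geometry ------------------------------------------------
  x0 <- to_search_scale(theta_init, scales)
  if (is.null(scan_bounds)) {
    scan_bounds <- if (scales[index] == "logit") c(1e-9, 1 - 1e-9) else c(1e-9, 1e9)
  }
  if (length(scan_bounds) != 2L || anyNA(scan_bounds) || scan_bounds[1] >= scan_bounds[2])
    stop("'scan_bounds' must be c(lower, upper) with lower < upper", call. = FALSE)
  sb <- to_search_scale(scan_bounds, rep(scales[index], 2L))
  if (!(sb[1] < x0[index] && x0[index] < sb[2]))
    stop(sprintf(paste0("theta_init[%d] = %g is not strictly inside scan_bounds (%g, %g); ",
                        "pass scan_bounds covering the start value"),
                 index, theta_init[index], scan_bounds[1], scan_bounds[2]),
         call. = FALSE)

  lo <- rep(-1e9, m); hi <- rep(1e9, m)
  if (!is.null(theta_bounds)) {
    theta_bounds <- as.matrix(theta_bounds)
    if (nrow(theta_bounds) != m || ncol(theta_bounds) != 2L)
      stop("'theta_bounds' must be an m x 2 matrix (natural scale)", call. = FALSE)
    for (k in seq_len(m)) {
      lo[k] <- to_search_scale(theta_bounds[k, 1], scales[k])
      hi[k] <- to_search_scale(theta_bounds[k, 2], scales[k])
    }
  }
  lo[index] <- max(lo[index], sb[1])
  hi[index] <- min(hi[index], sb[2])
  if (any(lo >= hi)) stop("empty parameter box after applying scan bounds", call. = FALSE)
  if (any(x0 < lo | x0 > hi))
    stop("'theta_init' lies outside 'theta_bounds'", call. = FALSE)

  sgn <- if (direction == "lower") 1 else -1
  faces <- c(lo[index], hi[index])

  # best feasible point seen anywhere during the search (search scale)
  best <- NULL
  best_obj <- Inf
  mu <- 0; rho <- 1

  eval_search <- function(x) {
    xc <- pmin(pmax(x, lo), hi)
    l <- ev(from_search_scale(xc, scales))
    if (is.finite(l) && l < crit - loss_tol) {
      obj <- sgn * xc[index]
      if (obj < best_obj) {
        best_obj <<- obj
        best <<- list(x = xc, x_i = xc[index], loss = l)
      }
    }
    list(xc = xc, l = l)
  }
  # pull-back term keeps the simplex near the box without changing the
  # constrained optimum (value outside the box >= value at the clamped point)
  aug <- function(x) {
    e <- eval_search(x)
    g <- e$l - crit
    sgn * e$xc[index] + al_penalty(g, mu, rho) + 100 * sum((x - e$xc)^2)
  }

  inner_maxit <- 200L * m + 200L
  inner_solve <- function(x) {
    if (local_alg == "nlminb") {
      res <- tryCatch(stats::nlminb(x, aug, lower = lo, upper = hi,
                                    control = list(iter.max = 300)),
                      error = function(e) NULL)
      if (!is.null(res)) return(pmin(pmax(res$par, lo), hi))
      return(x)
    }
    if (m == 1L) {
      # 1-D: golden-section over the box
      return(stats::optimize(function(t) aug(t), lower = lo, upper = hi,
                             tol = min(scan_tol / 10, 1e-6))$minimum)
    }
    res <- stats::optim(x, aug, method = "Nelder-Mead",
                        control = list(maxit = inner_maxit, reltol = 1e-10))
    pmin(pmax(res$par, lo), hi)
  }

  x <- x0
  prev_endpoint <- NA_real_
  prev_viol <- Inf
  status <- "MAX_ITER_STOP"
  stall_warned <- FALSE
  iters <- 0L

  for (it in seq_len(max_outer)) {
    iters <- it
    x <- inner_solve(x)
    e <- eval_search(x)
    x <- e$xc
    g <- e$l - crit
    viol <- max(0, if (is.finite(g)) g else Inf)
    endpoint_est <- x[index]
    if (verbose)
      message(sprintf("outer %3d: theta_%d = %.8g, l - crit = %.3g, mu = %.3g, rho = %.3g, calls = %d",
                      it, index, endpoint_est, g, mu, rho,
                      loss_calls(ev) - calls0))

    st <- certify_termination(best, endpoint_est, prev_endpoint, e$l,
                              direction, faces, crit, scan_tol, loss_tol)
    if (st != "CONTINUE") { status <- st; break }

    # s = dl/dtheta_i ~ 0 degeneracy: estimate stalled but constraint inactive
    if (!is.na(prev_endpoint) && abs(endpoint_est - prev_endpoint) < scan_tol &&
        is.finite(g) && g < -loss_tol && !stall_warned && it > 3L) {
      warning("endpoint estimate stalled with an inactive constraint; ",
              "the profile may be locally flat near the threshold - ",
              "consider lowering tolerances", call. = FALSE)
      stall_warned <- TRUE
    }

    if (loss_calls(ev) - calls0 >= max_evals) { status <- "MAX_ITER_STOP"; break }

    # multiplier update and penalty growth (Birgin-Martinez style schedule)
    mu <- max(0, mu + rho * (if (is.finite(g)) g else 0))
    if (viol > prev_viol / 4) rho <- min(rho * 10, 1e12)
    prev_viol <- viol
    prev_endpoint <- endpoint_est
  }

  found <- status == "BORDER_FOUND_BY_SCAN_TOL"
  tr <- NULL
  if (record_trace) {
    tr <- loss_trace(ev)
    tr <- tr[tr$eval_index > trace0, , drop = FALSE]
  }
  structure(
    list(
      endpoint = if (found) from_search_scale(x[index], scales[index]) else NA_real_,
      status = status,
      loss_calls = loss_calls(ev) - calls0,
      argument = if (found) from_search_scale(x, scales) else NULL,
      loss = if (found) e$l else NA_real_,
      certificate = if (status == "SCAN_BOUNDS_REACHED" && !is.null(best))
        from_search_scale(best$x, scales) else NULL,
      loss_crit = crit,
      l_min = l0,
      direction = direction,
      index = index,
      scale = scales[index],
      scan_bounds = scan_bounds,
      scan_tol = scan_tol,
      loss_tol = loss_tol,
      search_endpoint = if (found) x[index] else NA_real_,
      outer_iterations = iters,
      trace = tr
    ),
    class = "cico_endpoint"
  )
}

#' @export
print.cico_endpoint <- function(x, ...) {
  cat(sprintf("%s endpoint for parameter %d: ", x$direction, x$index))
  if (is.na(x$endpoint)) cat("not found") else cat(format(x$endpoint, digits = 6))
  cat(sprintf("\n  status: %s (%d loss calls, %d outer iterations)\n",
              x$status, x$loss_calls, x$outer_iterations))
  invisible(x)
}
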