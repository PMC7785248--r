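#' Stepwise profile likelihood (brute-force baseline)
#'
#' Computes the profile likelihood `l_PL(theta_i) = min over theta_{j != i} of
#' l(theta)` on a fixed grid by re-optimizing the nuisance parameters at every
#' grid point, sweeping outward from the start value in both directions with
#' warm starts (each re-optimization starts from the previous grid point's
#' nuisance argmin). This is the classic — and expensive — way to locate
#' confidence-interval endpoints; in this package it serves as the independent
#' oracle against which the constrained-optimization search is validated, and
#' as the curve drawn by [plot.cico()].
#'
#' @inheritParams find_endpoint
#' @param grid numeric vector of values for parameter `index`, sorted
#'   ascending, in the *search* scale (equal to the natural scale for
#'   `"direct"`). Must bracket the start value.
#' @param warm_start logical; `FALSE` restarts every nuisance re-optimization
#'   from `theta_init` (cold start), useful to probe re-optimization
#'   robustness.
#' @return an object of class `"cico_profile"`: list with `index`, `grid`,
#'   `values` (`l_PL` at each grid point, `+Inf` where re-optimization failed),
#'   `argmins` (matrix of full parameter vectors in search scale, one row per
#'   grid point), `theta_ref` (start value of parameter `index` in search
#'   scale), `scales` and `loss_calls`.
#' @examples
#' booth_profile <- profile_loss(booth, c(1, 3), index = 1,
#'                               grid = seq(-12, 13, by = 1))
#' # closed form: l_PL(theta_1) = 1.8 * (1 - theta_1)^2
#' @export
profile_loss <- function(loss, theta_init, index, grid,
                         scales = "direct",
                         local_alg = c("nelder-mead", "nlminb"),
                         warm_start = TRUE) {
  local_alg <- match.arg(local_alg)
  m <- length(theta_init)
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index > m)
    stop("'index' must be a single parameter index in 1..", m, call. = FALSE)
  index <- as.integer(index)
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be non-empty and strictly increasing", call. = FALSE)
  scales <- check_scales(scales, m)
  ev <- counted_loss(loss)
  calls0 <- loss_calls(ev)
  x0 <- to_search_scale(theta_init, scales)

  n <- length(grid)
  values <- rep(NA_real_, n)
  argmins <- matrix(NA_real_, nrow = n, ncol = m)

  eval_at <- function(ti, nuis) {
    x <- numeric(m)
    x[index] <- ti
    x[-index] <- nuis
    ev(from_search_scale(x, scales))
  }
  reoptimize <- function(ti, start_nuis) {
    if (m == 1L) return(list(value = eval_at(ti, numeric(0)), nuis = numeric(0)))
    res <- tryCatch({
      if (local_alg == "nlminb") {
        r <- stats::nlminb(start_nuis, function(nu) eval_at(ti, nu))
        list(value = r$objective, nuis = r$par)
      } else if (m == 2L) {
        r <- stats::optim(start_nuis, function(nu) eval_at(ti, nu),
                          method = "Brent",
                          lower = start_nuis - 1e6, upper = start_nuis + 1e6)
        list(value = r$value, nuis = r$par)
      } else {
        r <- stats::optim(start_nuis, function(nu) eval_at(ti, nu),
                          method = "Nelder-Mead",
                          control = list(maxit = 200L * m + 200L, reltol = 1e-10))
        list(value = r$value, nuis = r$par)
      }
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) {
      warning(sprintf("nuisance re-optimization failed at grid value %g", ti),
              call. = FALSE)
      return(list(value = Inf, nuis = start_nuis))
    }
    res
  }

  # sweep outward from the grid point nearest the start value
  k0 <- which.min(abs(grid - x0[index]))
  order_out <- c(seq(k0, n), if (k0 > 1) seq(k0 - 1, 1))
  nuis_right <- x0[-index]
  nuis <- nuis_right
  for (k in order_out) {
    if (k == k0 - 1) nuis <- nuis_right  # restart the left sweep from the MLE side
    start <- if (warm_start) nuis else x0[-index]
    res <- reoptimize(grid[k], start)
    values[k] <- res$value
    x <- numeric(m); x[index] <- grid[k]; x[-index] <- res$nuis
    argmins[k, ] <- x
    nuis <- res$nuis
    if (k == k0) nuis_right <- res$nuis
  }

  structure(
    list(index = index, grid = grid, values = values, argmins = argmins,
         theta_ref = x0[index], scales = scales,
         loss_calls = loss_calls(ev) - calls0),
    class = "cico_profile"
  )
}

#' @export
print.cico_profile <- function(x, ...) {
  cat(sprintf("profile likelihood of parameter %d on %d grid points (%d loss calls)\n",
              x$index, length(x$grid), x$loss_calls))
  cat(sprintf("  l_PL range: [%g, %g]\n", min(x$values), max(x$values[is.finite(x$values)])))
  invisible(x)
}

#' Threshold crossing of a computed profile
#'
#' Locates where the profile likelihood crosses the critical loss on one side
#' of the start value: the outermost sign change of `values - loss_crit` is
#' found and the crossing is linearly interpolated between the two bracketing
#' grid points. Returns `NA` when the profile stays below the threshold on
#' that side (non-identifiable within the grid).
#'
#' @param profile a `"cico_profile"` from [profile_loss()].
#' @param loss_crit finite scalar threshold.
#' @param side `"lower"` or `"upper"` — which side of the start value.
#' @return the interpolated crossing (search scale), or `NA_real_`.
#' @examples
#' pr <- profile_loss(booth, c(1, 3), index = 1, grid = seq(-12, 13, by = 0.5))
#' profile_crossing(pr, 200, "upper")  # ~ 1 + sqrt(200 / 1.8)
#' @export
profile_crossing <- function(profile, loss_crit, side = c("lower", "upper")) {
  side <- match.arg(side)
  stopifnot(inherits(profile, "cico_profile"))
  if (!is.numeric(loss_crit) || length(loss_crit) != 1L || !is.finite(loss_crit))
    stop("'loss_crit' must be a finite scalar", call. = FALSE)
  g <- profile$grid
  v <- profile$values
  ref <- profile$theta_ref
  if (ref < g[1] || ref > g[length(g)])
    stop("the profile grid does not bracket the start value", call. = FALSE)
  d <- v - loss_crit

  if (side == "upper") {
    idx <- which(g >= ref)
  } else {
    idx <- rev(which(g <= ref))  # ordered outward (decreasing theta)
  }
  if (length(idx) < 1L) return(NA_real_)
  # walk from the outermost pair inward; first bracket found is the outermost crossing
  if (length(idx) >= 2L) {
    for (j in seq(length(idx) - 1L, 1L)) {
      k_in <- idx[j]; k_out <- idx[j + 1L]
      din <- d[k_in]; dout <- d[k_out]
      if (!is.finite(din) && !is.finite(dout)) next
      if (dout == 0) return(g[k_out])
      if (din == 0 && dout > 0) return(g[k_in])
      if (din < 0 && dout > 0) {
        if (!is.finite(dout)) return(g[k_in])  # failure sentinel: report inner bracket
        return(g[k_in] + (0 - din) * (g[k_out] - g[k_in]) / (dout - din))
      }
    }
  }
  if (d[idx[1L]] == 0) return(g[idx[1L]])
  NA_real_
}
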