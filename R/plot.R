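#' Plot a likelihood profile with threshold and endpoints
#'
#' Draws the profile-likelihood curve, the horizontal critical-loss line, the
#' certified endpoints (filled red circles) and, for searches that hit the
#' scan bounds, a distinct black square at the certified bound point.
#' Optionally overlays the points visited by the endpoint search, which — by
#' design — need not lie on the profile path.
#'
#' @param profile a `"cico_profile"` from [profile_loss()].
#' @param loss_crit optional threshold to draw as a dashed horizontal line.
#' @param endpoints optional: a `"cico_interval"`, a `"cico_endpoint"` or a
#'   list of `"cico_endpoint"` objects for the profiled parameter.
#' @param trace optional data frame from a traced search (columns
#'   `theta_<index>` and `loss`), drawn as small grey points.
#' @param file optional path; when given the figure is written to a PNG file
#'   instead of the active device.
#' @param main,xlab,ylab usual graphics annotations.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the path (`file`) or `NULL`.
#' @export
plot_profile <- function(profile, loss_crit = NULL, endpoints = NULL,
                         trace = NULL, file = NULL,
                         main = sprintf("Profile likelihood of parameter %d", profile$index),
                         xlab = bquote(theta[.(profile$index)]),
                         ylab = "loss", ...) {
  stopifnot(inherits(profile, "cico_profile"))
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  ok <- is.finite(profile$values)
  ylim <- range(profile$values[ok], loss_crit, na.rm = TRUE)
  graphics::plot(profile$grid[ok], profile$values[ok], type = "l", lty = 3,
                 lwd = 2, main = main, xlab = xlab, ylab = ylab, ylim = ylim, ...)
  if (!is.null(trace) && nrow(trace) > 0) {
    col_i <- paste0("theta_", profile$index)
    if (col_i %in% names(trace))
      graphics::points(trace[[col_i]], pmin(trace$loss, ylim[2]),
                       pch = 16, cex = 0.4, col = "grey55")
  }
  if (!is.null(loss_crit))
    graphics::abline(h = loss_crit, lty = 2)
  eps <- endpoints
  if (inherits(eps, "cico_interval")) eps <- list(eps$lower, eps$upper)
  if (inherits(eps, "cico_endpoint")) eps <- list(eps)
  for (ep in eps) {
    if (ep$status == "BORDER_FOUND_BY_SCAN_TOL") {
      graphics::points(to_search_scale(ep$endpoint, ep$scale), ep$loss_crit,
                       pch = 19, col = "red", cex = 1.4)
    } else if (ep$status == "SCAN_BOUNDS_REACHED" && !is.null(ep$certificate)) {
      xi <- to_search_scale(ep$certificate[ep$index], ep$scale)
      yi <- min(profile$values[ok][which.min(abs(profile$grid[ok] - xi))], ylim[2])
      graphics::points(xi, yi, pch = 15, col = "black", cex = 1.4)
    }
  }
  invisible(file)
}

#' @describeIn cico plot the profile of one analyzed parameter with the fitted
#'   threshold and endpoint markers. The profile is computed on demand by
#'   [profile_loss()] on a grid spanning the found interval (padded by 20%) or
#'   the scan bounds when an endpoint was not found.
#' @param x a `"cico"` object.
#' @param npoints number of profile grid points.
#' @param file optional PNG path (see [plot_profile()]).
#' @export
plot.cico <- function(x, parm = x$parm[1], npoints = 41, file = NULL, ...) {
  iv <- x$intervals[[paste0("theta_", parm)]]
  if (is.null(iv)) stop("parameter ", parm, " was not analyzed", call. = FALSE)
  sc <- x$scales[parm]
  ref <- to_search_scale(x$theta_init[parm], sc)
  lo <- if (!is.na(iv$lower$endpoint))
    to_search_scale(iv$lower$endpoint, sc) else to_search_scale(iv$lower$scan_bounds[1], sc)
  hi <- if (!is.na(iv$upper$endpoint))
    to_search_scale(iv$upper$endpoint, sc) else to_search_scale(iv$upper$scan_bounds[2], sc)
  pad <- 0.2 * (hi - lo)
  grid <- seq(lo - pad, hi + pad, length.out = npoints)
  grid <- sort(unique(c(grid, ref)))
  pr <- profile_loss(x$loss, x$theta_init, index = parm, grid = grid,
                     scales = x$scales)
  plot_profile(pr, loss_crit = x$loss_crit, endpoints = iv, file = file, ...)
}
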