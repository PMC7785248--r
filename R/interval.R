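#' Confidence interval for one parameter
#'
#' Runs two independent endpoint searches ([find_endpoint()]), lower then
#' upper, both restarted from `theta_init`, and aggregates them. The parameter
#' is *practically identifiable within the scan bounds* iff both searches
#' certify an endpoint on the confidence-region boundary, i.e. the whole
#' interval lies strictly inside the declared feasible range.
#'
#' @inheritParams find_endpoint
#' @param ... further arguments passed to [find_endpoint()]
#'   (`theta_bounds`, `loss_tol`, `max_evals`, `local_alg`, `record_trace`,
#'   `max_outer`, `verbose`).
#' @return an object of class `"cico_interval"`: list with `lower` and `upper`
#'   (class `"cico_endpoint"`), `identifiable_within_bounds`, `index`,
#'   `loss_crit` and `loss_calls` (total over both searches).
#' @examples
#' q <- function(th) 5 + (th[1] - 3)^2 + (th[1] - th[2] - 1)^2
#' ci <- find_interval(q, c(3, 2), index = 1, loss_crit = 9,
#'                     scan_bounds = c(-50, 50))
#' c(ci$lower$endpoint, ci$upper$endpoint)  # ~[1, 5]
#' @seealso [cico()] for several parameters at once.
#' @export
find_interval <- function(loss, theta_init, index,
                          loss_crit = NULL, alpha = 0.95, df = 1,
                          scan_bounds = NULL, scales = "direct",
                          scan_tol = 1e-3, ...) {
  ev <- counted_loss(loss, record_trace = isTRUE(list(...)$record_trace))
  lower <- find_endpoint(ev, theta_init, index, direction = "lower",
                         loss_crit = loss_crit, alpha = alpha, df = df,
                         scan_bounds = scan_bounds, scales = scales,
                         scan_tol = scan_tol, ...)
  upper <- find_endpoint(ev, theta_init, index, direction = "upper",
                         loss_crit = loss_crit, alpha = alpha, df = df,
                         scan_bounds = scan_bounds, scales = scales,
                         scan_tol = scan_tol, ...)
  structure(
    list(
      lower = lower,
      upper = upper,
      identifiable_within_bounds =
        lower$status == "BORDER_FOUND_BY_SCAN_TOL" &&
        upper$status == "BORDER_FOUND_BY_SCAN_TOL",
      index = lower$index,
      loss_crit = lower$loss_crit,
      loss_calls = lower$loss_calls + upper$loss_calls
    ),
    class = "cico_interval"
  )
}

#' @export
print.cico_interval <- function(x, ...) {
  fmt <- function(ep) if (is.na(ep$endpoint)) sprintf("(%s)", ep$status)
    else format(ep$endpoint, digits = 6)
  cat(sprintf("parameter %d: [%s, %s]  loss_crit = %g, %d loss calls\n",
              x$index, fmt(x$lower), fmt(x$upper), x$loss_crit, x$loss_calls))
  cat(sprintf("  practically identifiable within bounds: %s\n",
              x$identifiable_within_bounds))
  invisible(x)
}

#' Practical identifiability analysis by constrained optimization
#'
#' The main entry point. For each requested parameter, both endpoints of the
#' profile-likelihood confidence interval
#' `{theta_i : l_PL(theta_i) <= l(theta_hat) + Delta_alpha}` are found directly
#' as solutions of the constrained problems "minimize `+-theta_i` subject to
#' `l(theta) <= loss_crit`", without tracing the likelihood profile. See
#' [find_endpoint()] for the algorithm and its termination statuses.
#'
#' @inheritParams find_endpoint
#' @param parm integer vector of parameter indices to analyze (default: all).
#' @param scan_bounds either a length-2 vector applied to every analyzed
#'   parameter or a list of length-2 vectors indexed like `theta_init`
#'   (natural scale).
#' @param ... further arguments passed to [find_endpoint()].
#' @return an object of class `"cico"`: list with `intervals` (one
#'   `"cico_interval"` per element of `parm`), `theta_init`, `parm`,
#'   `loss_crit`, `alpha`, `df`, `scales`, `loss_calls` and the matched call.
#'   Methods: `print()`, [summary.cico()], `coef()`, `confint()` and
#'   [plot.cico()].
#' @examples
#' q <- function(th) 5 + (th[1] - 3)^2 + (th[1] - th[2] - 1)^2
#' fit <- cico(q, theta_init = c(3, 2), loss_crit = 9, scan_bounds = c(-50, 50))
#' fit
#' coef(fit)
#' @export
cico <- function(loss, theta_init, parm = seq_along(theta_init),
                 loss_crit = NULL, alpha = 0.95, df = 1,
                 scan_bounds = NULL, scales = "direct",
                 scan_tol = 1e-3, ...) {
  m <- length(theta_init)
  if (length(parm) < 1L || any(parm < 1 | parm > m))
    stop("'parm' must be a non-empty set of indices in 1..", m, call. = FALSE)
  parm <- as.integer(parm)
  ev <- counted_loss(loss, record_trace = isTRUE(list(...)$record_trace))
  sb_for <- function(i) {
    if (is.null(scan_bounds)) return(NULL)
    if (is.list(scan_bounds)) return(scan_bounds[[i]])
    scan_bounds
  }
  intervals <- lapply(parm, function(i)
    find_interval(ev, theta_init, index = i,
                  loss_crit = loss_crit, alpha = alpha, df = df,
                  scan_bounds = sb_for(i), scales = scales,
                  scan_tol = scan_tol, ...))
  names(intervals) <- paste0("theta_", parm)
  structure(
    list(
      intervals = intervals,
      theta_init = theta_init,
      parm = parm,
      loss_crit = intervals[[1]]$loss_crit,
      alpha = if (is.null(loss_crit)) alpha else NA_real_,
      df = if (is.null(loss_crit)) df else NA_integer_,
      scales = check_scales(scales, m),
      loss = ev,
      loss_calls = sum(vapply(intervals, `[[`, 0, "loss_calls")),
      call = match.call()
    ),
    class = "cico"
  )
}

#' @export
print.cico <- function(x, digits = 6, ...) {
  cat("Confidence intervals by constrained optimization\n")
  if (!is.na(x$alpha))
    cat(sprintf("  confidence level %.3g (chi-square df = %d), loss_crit = %.6g\n",
                x$alpha, x$df, x$loss_crit))
  else
    cat(sprintf("  loss_crit = %.6g\n", x$loss_crit))
  print(summary(x)$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summarize a cico analysis
#'
#' @param object a `"cico"` object.
#' @param ... unused.
#' @return an object of class `"summary.cico"` whose `table` element is a data
#'   frame with one row per analyzed parameter: point estimate, endpoints
#'   (`NA` where not found), termination statuses, identifiability flag and
#'   loss-call counts.
#' @export
summary.cico <- function(object, ...) {
  rows <- lapply(object$intervals, function(iv) {
    data.frame(
      parameter = iv$index,
      estimate = object$theta_init[iv$index],
      lower = iv$lower$endpoint,
      upper = iv$upper$endpoint,
      status_lower = iv$lower$status,
      status_upper = iv$upper$status,
      identifiable = iv$identifiable_within_bounds,
      loss_calls = iv$loss_calls,
      stringsAsFactors = FALSE
    )
  })
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 loss_crit = object$loss_crit, alpha = object$alpha,
                 df = object$df, loss_calls = object$loss_calls),
            class = "summary.cico")
}

#' @export
print.summary.cico <- function(x, digits = 6, ...) {
  cat("Practical identifiability summary\n")
  cat(sprintf("  loss_crit = %.6g, total loss calls = %d\n", x$loss_crit, x$loss_calls))
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname summary.cico
#' @return `coef()`: a matrix with columns `lower`, `upper`, one row per
#'   analyzed parameter (`NA` for endpoints not found).
coef.cico <- function(object, ...) {
  out <- t(vapply(object$intervals,
                  function(iv) c(lower = iv$lower$endpoint,
                                 upper = iv$upper$endpoint),
                  numeric(2)))
  rownames(out) <- names(object$intervals)
  out
}

#' @export
#' @rdname summary.cico
#' @param parm indices (or `theta_<i>` names) of parameters to extract.
#' @param level ignored; the level is fixed when the object is fitted.
confint.cico <- function(object, parm, level, ...) {
  out <- coef.cico(object)
  if (!missing(parm)) {
    if (is.numeric(parm)) parm <- paste0("theta_", as.integer(parm))
    out <- out[rownames(out) %in% parm, , drop = FALSE]
  }
  out
}
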