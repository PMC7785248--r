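#' Wrap a loss function into a counted, guarded evaluator
#'
#' All routines in this package consume the negative log-likelihood through a
#' counted evaluator: every call (including failed ones) increments a counter,
#' and any evaluation that errors or returns a non-finite / non-scalar value is
#' reported as `+Inf` rather than propagated as an error. The `+Inf` sentinel
#' lets derivative-free optimizers step through regions where, e.g., an ODE
#' solver would fail, instead of aborting the endpoint search.
#'
#' The call count is the hardware- and language-independent cost metric used
#' throughout: the number of loss-function (likelihood) evaluations.
#'
#' @param fn a function mapping a numeric parameter vector to a scalar loss
#'   (typically `-2 log` likelihood, or a weighted sum of squared residuals).
#'   If `fn` is already a counted evaluator it is returned unchanged.
#' @param record_trace logical; if `TRUE`, every evaluated point and its loss
#'   are kept and can be retrieved with [loss_trace()].
#' @return a function of class `"counted_loss"`; call it like the original
#'   loss. Query it with [loss_calls()] and [loss_trace()].
#' @examples
#' ev <- counted_loss(function(th) sum(th^2))
#' ev(c(1, 2))
#' loss_calls(ev)
#' @seealso [loss_threshold()], [find_interval()]
#' @export
counted_loss <- function(fn, record_trace = FALSE) {
  if (inherits(fn, "counted_loss")) return(fn)
  stopifnot(is.function(fn))
  raw <- fn
  count <- 0L
  trace <- if (isTRUE(record_trace)) vector("list", 0L) else NULL
  ev <- function(theta) {
    count <<- count + 1L
    val <- tryCatch(raw(theta), error = function(e) Inf)
    val <- suppressWarnings(as.numeric(val))
    if (length(val) != 1L || is.na(val) || !is.finite(val)) val <- Inf
    if (!is.null(trace)) trace[[length(trace) + 1L]] <<- c(theta, val)
    val
  }
  class(ev) <- c("counted_loss", "function")
  ev
}

#' @rdname counted_loss
#' @param x a `"counted_loss"` evaluator.
#' @return `loss_calls()`: the number of evaluations performed so far.
#' @export
loss_calls <- function(x) {
  stopifnot(inherits(x, "counted_loss"))
  environment(x)$count
}

#' @rdname counted_loss
#' @return `loss_trace()`: a data frame with columns `eval_index`,
#'   `theta_1 ... theta_m` and `loss` (zero rows when tracing was off).
#' @export
loss_trace <- function(x) {
  stopifnot(inherits(x, "counted_loss"))
  tr <- environment(x)$trace
  if (is.null(tr) || length(tr) == 0L) {
    return(data.frame(eval_index = integer(0), loss = numeric(0)))
  }
  mat <- do.call(rbind, tr)
  m <- ncol(mat) - 1L
  out <- data.frame(eval_index = seq_len(nrow(mat)))
  for (j in seq_len(m)) out[[paste0("theta_", j)]] <- mat[, j]
  out$loss <- mat[, m + 1L]
  out
}

#' Likelihood-ratio threshold for confidence-interval endpoints
#'
#' The confidence region at level `alpha` is `{theta : l(theta) <= loss_crit}`
#' with `loss_crit = l_min + delta`, where `l_min` is the loss at the best fit
#' and `delta` is the `alpha` quantile of the chi-square distribution with
#' `df` degrees of freedom (likelihood-ratio test). `df = 1` gives the usual
#' pointwise interval for a single parameter; `df = m` would give the
#' simultaneous (projection) interval.
#'
#' A pre-computed `loss_crit` may be supplied directly, mirroring interfaces
#' that take the critical loss value itself; it then takes precedence over
#' `alpha`/`df`.
#'
#' @param l_min finite scalar, the loss at the fitted optimum `l(theta_hat)`.
#' @param alpha confidence level in (0, 1). Default 0.95.
#' @param df positive integer degrees of freedom for the chi-square quantile.
#' @param loss_crit optional scalar critical loss; overrides `alpha`/`df`.
#' @return an object of class `"loss_threshold"`: a list with `l_min`,
#'   `alpha`, `df`, `delta` (`loss_crit - l_min`) and `loss_crit`.
#' @examples
#' loss_threshold(5, alpha = 0.95, df = 1)   # loss_crit = 5 + 3.841...
#' loss_threshold(5, loss_crit = 9)          # explicit critical value
#' @export
loss_threshold <- function(l_min, alpha = 0.95, df = 1, loss_crit = NULL) {
  if (!is.numeric(l_min) || length(l_min) != 1L || !is.finite(l_min))
    stop("'l_min' must be a finite scalar", call. = FALSE)
  if (!is.null(loss_crit)) {
    if (!is.numeric(loss_crit) || length(loss_crit) != 1L || !is.finite(loss_crit))
      stop("'loss_crit' must be a finite scalar", call. = FALSE)
    delta <- loss_crit - l_min
    alpha <- NA_real_
    df <- NA_integer_
  } else {
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha <= 0 || alpha >= 1)
      stop("'alpha' must lie strictly inside (0, 1)", call. = FALSE)
    if (!is.numeric(df) || length(df) != 1L || is.na(df) || df < 1)
      stop("'df' must be a positive integer", call. = FALSE)
    df <- as.integer(df)
    delta <- stats::qchisq(alpha, df = df)
    loss_crit <- l_min + delta
  }
  structure(
    list(l_min = l_min, alpha = alpha, df = df, delta = delta,
         loss_crit = loss_crit),
    class = "loss_threshold"
  )
}

#' @export
print.loss_threshold <- function(x, ...) {
  cat("Likelihood-ratio threshold\n")
  cat(sprintf("  l_min     = %.6g\n", x$l_min))
  if (!is.na(x$alpha))
    cat(sprintf("  alpha, df = %.4g, %d\n", x$alpha, x$df))
  cat(sprintf("  delta     = %.6g\n", x$delta))
  cat(sprintf("  loss_crit = %.6g\n", x$loss_crit))
  invisible(x)
}
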