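#' Parameter scales: map between natural and search space
#'
#' The endpoint search can run in a transformed space per parameter, which
#' often conditions strongly nonlinear likelihoods much better. Three scales
#' are supported:
#'
#' * `"direct"` — identity;
#' * `"log"` — base-10 logarithm, for strictly positive parameters
#'   (rate constants spanning orders of magnitude);
#' * `"logit"` — `log(x / (1 - x))` (natural log), for parameters strictly
#'   inside (0, 1) such as fractions.
#'
#' All three maps are strictly increasing, so endpoint ordering is preserved
#' across scales. Scan bounds and tolerances are interpreted in the search
#' scale; reported endpoints are mapped back to the natural scale.
#'
#' @param value numeric vector of parameter values.
#' @param scale character vector of scales, one of `"direct"`, `"log"`,
#'   `"logit"`; recycled to the length of `value`.
#' @return numeric vector of the same length as `value`.
#' @examples
#' to_search_scale(100, "log")        # 2
#' to_search_scale(0.5, "logit")      # 0
#' from_search_scale(2, "log")        # 100
#' @export
to_search_scale <- function(value, scale = "direct") {
  scale <- check_scales(scale, length(value))
  out <- value
  for (k in seq_along(value)) {
    v <- value[k]
    out[k] <- switch(scale[k],
      direct = v,
      log = {
        if (!is.na(v) && v <= 0)
          stop(sprintf("parameter %d: log scale requires strictly positive values (got %g)",
                       k, v), call. = FALSE)
        log10(v)
      },
      logit = {
        if (!is.na(v) && (v <= 0 || v >= 1))
          stop(sprintf("parameter %d: logit scale requires values strictly inside (0, 1) (got %g)",
                       k, v), call. = FALSE)
        stats::qlogis(v)
      }
    )
  }
  out
}

#' @rdname to_search_scale
#' @export
from_search_scale <- function(value, scale = "direct") {
  scale <- check_scales(scale, length(value))
  out <- value
  for (k in seq_along(value)) {
    v <- value[k]
    out[k] <- switch(scale[k],
      direct = v,
      log = 10^v,
      logit = stats::plogis(v)
    )
  }
  out
}

# normalize/validate a scale spec to length m
check_scales <- function(scale, m) {
  if (is.null(scale)) scale <- "direct"
  scale <- as.character(scale)
  bad <- setdiff(unique(scale), c("direct", "log", "logit"))
  if (length(bad))
    stop("unknown scale(s): ", paste(bad, collapse = ", "),
         " (use 'direct', 'log' or 'logit')", call. = FALSE)
  if (length(scale) == 1L) scale <- rep(scale, m)
  if (length(scale) != m)
    stop(sprintf("'scales' has length %d but there are %d parameters",
                 length(scale), m), call. = FALSE)
  scale
}
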