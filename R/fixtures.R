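#' Bundled toy objectives
#'
#' Three small two-parameter objectives used throughout the tests, examples
#' and documentation:
#'
#' * `booth(theta)` = `(t1 + 2*t2 - 7)^2 + (2*t1 + t2 - 5)^2`, minimum 0 at
#'   (1, 3). Its profile over either parameter is closed-form quadratic
#'   (`l_PL(t1) = 1.8 * (1 - t1)^2`), so endpoints at any threshold are known
#'   analytically — an identifiable test case.
#' * `rosenbrock(theta)` = `(1 - t1)^2 + 100 * (t2 - t1^2)^2`, minimum 0 at
#'   (1, 1). Its profile over `t1` is `(1 - t1)^2`, which stays far below a
#'   threshold of 200 on any moderate range — the canonical
#'   non-identifiable-within-bounds case.
#' * `quadratic_loss(theta)` = `5 + (t1 - 3)^2 + (t1 - t2 - 1)^2`, minimum 5
#'   at (3, 2). With `loss_crit = 9` the intervals are `[1, 5]` for `t1` and
#'   `[2 - 2*sqrt(2), 2 + 2*sqrt(2)]` for `t2` (analytic).
#'
#' @param theta numeric vector of length 2.
#' @return scalar objective value.
#' @examples
#' booth(c(1, 3))          # 0
#' rosenbrock(c(1, 1))     # 0
#' quadratic_loss(c(3, 2)) # 5
#' @export
booth <- function(theta) {
  stopifnot(length(theta) == 2L)
  (theta[1] + 2 * theta[2] - 7)^2 + (2 * theta[1] + theta[2] - 5)^2
}

#' @rdname booth
#' @export
rosenbrock <- function(theta) {
  stopifnot(length(theta) == 2L)
  (1 - theta[1])^2 + 100 * (theta[2] - theta[1]^2)^2
}

#' @rdname booth
#' @export
quadratic_loss <- function(theta) {
  stopifnot(length(theta) == 2L)
  5 + (theta[1] - 3)^2 + (theta[1] - theta[2] - 1)^2
}

#' Ready-made endpoint-search test problems
#'
#' Packages each toy objective together with its start point, a critical loss
#' value, suggested scan bounds and the analytically known endpoints (where
#' they exist), so the same problems can be driven from tests, examples and
#' the command-line runner.
#'
#' @param name one of `"quadratic"`, `"booth"`, `"rosenbrock"`.
#' @return a list with `name`, `loss`, `theta_init`, `loss_crit`,
#'   `scan_bounds` and `known_endpoints` (a list with one `c(lower, upper)`
#'   per parameter; `NA` entries where no finite endpoint exists within the
#'   suggested scan bounds, `NULL` where no closed form is catalogued).
#' @examples
#' tp <- toy_problem("quadratic")
#' tp$known_endpoints[[1]]  # c(1, 5)
#' @export
toy_problem <- function(name = c("quadratic", "booth", "rosenbrock")) {
  name <- match.arg(name)
  switch(name,
    quadratic = list(
      name = "quadratic",
      loss = quadratic_loss,
      theta_init = c(3, 2),
      loss_crit = 9,
      scan_bounds = c(-50, 50),
      known_endpoints = list(c(1, 5), c(2 - 2 * sqrt(2), 2 + 2 * sqrt(2)))
    ),
    booth = list(
      name = "booth",
      loss = booth,
      theta_init = c(1, 3),
      loss_crit = 200,
      scan_bounds = c(-30, 30),
      # profiles: l_PL(t1) = 1.8 (1 - t1)^2, l_PL(t2) = 1.8 (t2 - 3)^2
      known_endpoints = list(1 + c(-1, 1) * sqrt(200 / 1.8),
                             3 + c(-1, 1) * sqrt(200 / 1.8))
    ),
    rosenbrock = list(
      name = "rosenbrock",
      loss = rosenbrock,
      theta_init = c(1, 1),
      loss_crit = 200,
      scan_bounds = c(-5, 5),
      # l_PL(t1) = (1 - t1)^2 <= 36 < 200 on (-5, 5): no crossing within bounds
      known_endpoints = list(c(NA_real_, NA_real_), NULL)
    )
  )
}
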