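# endpoint search on problems with analytically known answers

test_that("augmented objective reduces to the target at zero penalty and on the boundary", {
  # interior feasible point, mu = 0, rho -> 0: objective is +-theta_i exactly
  expect_equal(augmented_objective(c(3, 2), mu = 0, rho = 0, loss = quadratic_loss,
                                   index = 1, direction = "lower", loss_crit = 9), 3)
  expect_equal(augmented_objective(c(3, 2), mu = 0, rho = 0, loss = quadratic_loss,
                                   index = 1, direction = "upper", loss_crit = 9), -3)
  # point exactly on the constraint (g = 0): psi vanishes for any mu, rho
  # quadratic at (1, 0): l = 5 + 4 + 0 = 9
  expect_equal(augmented_objective(c(1, 0), mu = 1, rho = 0, loss = quadratic_loss,
                                   index = 1, direction = "lower", loss_crit = 9), 1)
  expect_equal(augmented_objective(c(1, 0), mu = 3, rho = 7, loss = quadratic_loss,
                                   index = 2, direction = "upper", loss_crit = 9), 0)
  # infeasible point: mu*g + rho/2 g^2 branch
  # quadratic at (3, 0): l = 9, crit = 7 -> g = 2
  expect_equal(augmented_objective(c(3, 0), mu = 1, rho = 4, loss = quadratic_loss,
                                   index = 1, direction = "lower", loss_crit = 7),
               3 + 1 * 2 + 2 * 4)
  # deeply feasible with active multiplier memory: -mu^2 / (2 rho) branch
  # quadratic at minimum: g = 5 - 9 = -4 < -mu/rho = -1
  expect_equal(augmented_objective(c(3, 2), mu = 2, rho = 2, loss = quadratic_loss,
                                   index = 1, direction = "lower", loss_crit = 9),
               3 - 4 / 4)
})

test_that("quadratic endpoints match the analytic constrained optima", {
  tp <- toy_problem("quadratic")
  for (i in 1:2) {
    iv <- find_interval(tp$loss, tp$theta_init, index = i, loss_crit = tp$loss_crit,
                        scan_bounds = tp$scan_bounds)
    expect_equal(iv$lower$status, "BORDER_FOUND_BY_SCAN_TOL")
    expect_equal(iv$upper$status, "BORDER_FOUND_BY_SCAN_TOL")
    expect_true(iv$identifiable_within_bounds)
    expect_equal(iv$lower$endpoint, tp$known_endpoints[[i]][1], tolerance = 1e-3)
    expect_equal(iv$upper$endpoint, tp$known_endpoints[[i]][2], tolerance = 1e-3)
    # loss-call accounting: interval total is the sum of its two searches
    expect_equal(iv$loss_calls, iv$lower$loss_calls + iv$upper$loss_calls)
  }
})

test_that("Booth endpoints match the closed-form profile crossings", {
  tp <- toy_problem("booth")
  for (i in 1:2) {
    iv <- find_interval(tp$loss, tp$theta_init, index = i, loss_crit = 200,
                        scan_bounds = tp$scan_bounds)
    expect_equal(iv$lower$endpoint, tp$known_endpoints[[i]][1], tolerance = 1e-4)
    expect_equal(iv$upper$endpoint, tp$known_endpoints[[i]][2], tolerance = 1e-4)
  }
})

test_that("Rosenbrock within (-5, 5) is certified non-identifiable in both directions", {
  tp <- toy_problem("rosenbrock")
  iv <- find_interval(tp$loss, tp$theta_init, index = 1, loss_crit = 200,
                      scan_bounds = c(-5, 5))
  expect_equal(iv$lower$status, "SCAN_BOUNDS_REACHED")
  expect_equal(iv$upper$status, "SCAN_BOUNDS_REACHED")
  expect_false(iv$identifiable_within_bounds)
  expect_true(is.na(iv$lower$endpoint))
  expect_true(is.na(iv$upper$endpoint))
  # each certificate is a feasible point at the scan-bound face
  for (side in c("lower", "upper")) {
    cert <- iv[[side]]$certificate
    expect_false(is.null(cert))
    expect_lt(rosenbrock(cert), 200)
    face <- if (side == "lower") -5 else 5
    expect_lt(abs(cert[1] - face), 1e-3 + 1e-8)
  }
})

test_that("found endpoints sit on the confidence-region boundary and bracket the start", {
  # constraint activity + bracketing across fixtures and thresholds
  cases <- expand.grid(name = c("quadratic", "booth"), index = 1:2,
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    tp <- toy_problem(cases$name[r])
    i <- cases$index[r]
    iv <- find_interval(tp$loss, tp$theta_init, index = i, loss_crit = tp$loss_crit,
                        scan_bounds = tp$scan_bounds)
    for (side in c("lower", "upper")) {
      ep <- iv[[side]]
      expect_equal(ep$status, "BORDER_FOUND_BY_SCAN_TOL")
      expect_lte(abs(tp$loss(ep$argument) - tp$loss_crit), ep$loss_tol)
      expect_true(ep$endpoint > tp$scan_bounds[1] && ep$endpoint < tp$scan_bounds[2])
    }
    expect_lte(iv$lower$endpoint, tp$theta_init[i])
    expect_gte(iv$upper$endpoint, tp$theta_init[i])
  }
})

test_that("raising the threshold never shrinks a found interval", {
  for (name in c("quadratic", "booth")) {
    tp <- toy_problem(name)
    l_min <- tp$loss(tp$theta_init)
    crits <- l_min + c(2, 6, 20)
    widths <- matrix(NA_real_, nrow = 3, ncol = 2)
    prev <- NULL
    for (k in seq_along(crits)) {
      iv <- find_interval(tp$loss, tp$theta_init, index = 1, loss_crit = crits[k],
                          scan_bounds = c(-100, 100))
      cur <- c(iv$lower$endpoint, iv$upper$endpoint)
      if (!is.null(prev)) {
        expect_lte(cur[1], prev[1] + 1e-6)
        expect_gte(cur[2], prev[2] - 1e-6)
      }
      prev <- cur
    }
  }
})

test_that("endpoints found in log scale agree with direct-scale endpoints", {
  # positive-parameter problem: quadratic theta_1 endpoints are 1 and 5
  scan_tol <- 1e-3
  iv_d <- find_interval(quadratic_loss, c(3, 2), index = 1, loss_crit = 9,
                        scan_bounds = c(1e-3, 50), scan_tol = scan_tol)
  iv_l <- find_interval(quadratic_loss, c(3, 2), index = 1, loss_crit = 9,
                        scan_bounds = c(1e-3, 50), scales = c("log", "direct"),
                        scan_tol = scan_tol)
  expect_equal(iv_l$lower$endpoint, iv_d$lower$endpoint, tolerance = 10 * scan_tol)
  expect_equal(iv_l$upper$endpoint, iv_d$upper$endpoint, tolerance = 10 * scan_tol)
})

test_that("a barely-above-minimum threshold collapses the interval onto the start", {
  iv <- find_interval(quadratic_loss, c(3, 2), index = 1, loss_crit = 5 + 1e-6,
                      scan_bounds = c(-50, 50), scan_tol = 1e-3)
  expect_true(iv$identifiable_within_bounds)
  expect_equal(iv$lower$endpoint, 3, tolerance = 5e-3)
  expect_equal(iv$upper$endpoint, 3, tolerance = 5e-3)
})

test_that("an infeasible start is rejected with advice, invalid settings error", {
  expect_error(find_endpoint(quadratic_loss, c(10, 0), index = 1, loss_crit = 9,
                             scan_bounds = c(-50, 50)),
               "infeasible")
  expect_error(find_endpoint(quadratic_loss, c(3, 2), index = 3, loss_crit = 9),
               "index")
  expect_error(find_endpoint(quadratic_loss, c(3, 2), index = 1, loss_crit = 9,
                             scan_bounds = c(5, 50)),
               "scan_bounds")
  expect_error(find_endpoint(quadratic_loss, c(3, 2), index = 1, loss_crit = 9,
                             scan_bounds = c(-50, 50), scan_tol = 0),
               "scan_tol")
})

test_that("an exhausted budget reports MAX_ITER_STOP without an endpoint", {
  iv <- find_endpoint(quadratic_loss, c(3, 2), index = 1, loss_crit = 9,
                      scan_bounds = c(-50, 50), max_evals = 5, max_outer = 1)
  expect_equal(iv$status, "MAX_ITER_STOP")
  expect_true(is.na(iv$endpoint))
})

test_that("termination certification follows its definitions", {
  # feasible point pinned at the lower face, loss well below threshold
  expect_equal(
    cico:::certify_termination(
      best_feasible = list(x_i = -5, loss = 190 - 10 * 0.2),
      endpoint_est = -4.9, prev_endpoint = -4.0, loss_at_est = 150,
      direction = "lower", faces = c(-5, 5),
      loss_crit = 200, scan_tol = 1e-3, loss_tol = 0.2),
    "SCAN_BOUNDS_REACHED")
  # successive estimates within scan_tol/10, loss within loss_tol of threshold
  expect_equal(
    cico:::certify_termination(
      best_feasible = NULL,
      endpoint_est = 1.00001, prev_endpoint = 1.0001, loss_at_est = 200.1,
      direction = "upper", faces = c(-5, 5),
      loss_crit = 200, scan_tol = 1e-3, loss_tol = 0.2),
    "BORDER_FOUND_BY_SCAN_TOL")
  # neither certificate: continue
  expect_equal(
    cico:::certify_termination(
      best_feasible = list(x_i = 2, loss = 100),
      endpoint_est = 2, prev_endpoint = 3, loss_at_est = 100,
      direction = "upper", faces = c(-5, 5),
      loss_crit = 200, scan_tol = 1e-3, loss_tol = 0.2),
    "CONTINUE")
})

test_that("the search works on a one-parameter loss (empty nuisance set)", {
  f <- function(th) (th[1] - 2)^2
  iv <- find_interval(f, 2, index = 1, loss_crit = 4, scan_bounds = c(-50, 50))
  expect_equal(iv$lower$endpoint, 0, tolerance = 1e-3)
  expect_equal(iv$upper$endpoint, 4, tolerance = 1e-3)
})

test_that("cico() aggregates per-parameter intervals with methods", {
  tp <- toy_problem("quadratic")
  fit <- cico(tp$loss, tp$theta_init, loss_crit = 9, scan_bounds = tp$scan_bounds)
  cm <- coef(fit)
  expect_equal(dim(cm), c(2L, 2L))
  expect_equal(unname(cm["theta_1", ]), c(1, 5), tolerance = 1e-3)
  expect_equal(unname(cm["theta_2", ]), c(2 - 2 * sqrt(2), 2 + 2 * sqrt(2)),
               tolerance = 1e-3)
  expect_identical(confint(fit), cm)
  expect_equal(unname(confint(fit, parm = 2)[1, ]), unname(cm[2, ]))
  s <- summary(fit)
  expect_s3_class(s, "summary.cico")
  expect_true(all(s$table$identifiable))
  expect_equal(s$table$estimate, c(3, 2))
  expect_output(print(fit), "Confidence intervals by constrained optimization")
  expect_error(cico(tp$loss, tp$theta_init, parm = integer(0), loss_crit = 9),
               "parm")
})
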