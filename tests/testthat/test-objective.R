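## noiseless identity-mapped data: the spline can represent the truth
## exactly, so residuals vanish at the true parameters
make_noiseless_t1 <- function(sigma_known = 0.05) {
  pr <- t1_protocol()
  model <- build_fret_model(pr$PTOT)
  ds <- generate_dataset(model, pr$theta_true, pr$times,
                         mappings = list(active_fraction = function(y) y),
                         sigma = c(active_fraction = 0), seed = 1)
  cfg <- list(observable_config("active_fraction", "nonlinear_monotone",
                                noise_mode = "known",
                                known_sigma = sigma_known, lambda = 0))
  hier_objective(model, ds$data, cfg)
}

test_that("noiseless representable data at true theta gives J equal to the normalization constant", {
  obj <- make_noiseless_t1(0.05)
  pr <- t1_protocol()
  ev <- evaluate_objective(obj, pr$theta_true_log10)
  nt <- 12
  expect_lt(max(abs(ev$inner$active_fraction$residuals)), 1e-6)
  expect_equal(ev$J, nt * 0.5 * log(2 * pi * 0.05^2), tolerance = 1e-4)
})

test_that("duplicating every measurement doubles the data-dependent part of J", {
  fx <- t1_fixture()
  cfgk <- list(observable_config("active_fraction", "nonlinear_monotone",
                                 noise_mode = "known", known_sigma = 0.05,
                                 lambda = 0))
  obj1 <- hier_objective(fx$ds$model, fx$ds$data, cfgk,
                         fixed_knots = fx$fixed_knots)
  obj2 <- hier_objective(fx$ds$model, rbind(fx$ds$data, fx$ds$data), cfgk,
                         fixed_knots = fx$fixed_knots)
  th <- fx$pr$theta_true_log10
  J1 <- evaluate_objective(obj1, th, with_gradient = FALSE)$J
  J2 <- evaluate_objective(obj2, th, with_gradient = FALSE)$J
  expect_equal(J2, 2 * J1, tolerance = 1e-9)
})

test_that("hierarchical J matches an independently coded flat NLL at (theta, psi*)", {
  fx <- t1_fixture()
  obj <- hier_objective(fx$ds$model, fx$ds$data, fx$cfg,
                        fixed_knots = fx$fixed_knots)
  th <- fx$pr$theta_true_log10 + c(0.05, -0.03, 0, 0)
  ev <- evaluate_objective(obj, th, with_gradient = FALSE)
  sol <- ev$inner$active_fraction
  ## flat NLL written from scratch
  y <- sol$y; z <- fx$ds$data$measurement
  knot_x <- c(0, sol$mapping$knots)
  knot_y <- c(0, cumsum(sol$psi))
  s_of_y <- approx(knot_x, knot_y, xout = pmin(y, max(knot_x)), rule = 2)$y
  nll <- sum(0.5 * log(2 * pi * sol$sigma^2) +
               (s_of_y - z)^2 / (2 * sol$sigma^2)) +
    0.5 * 1e-2 * sum((sol$psi - mean(sol$psi))^2)
  expect_equal(ev$J, nll, tolerance = 1e-10)
})

test_that("gradient vanishes at a zero-residual point and for unused parameters", {
  obj <- make_noiseless_t1(0.05)
  pr <- t1_protocol()
  ev <- evaluate_objective(obj, pr$theta_true_log10)
  ## alpha, beta do not enter the spline-fitted active_fraction observable
  expect_equal(ev$gradient[3:4], c(0, 0))
  ## residuals are at integrator-noise level, so the gradient is ~0
  expect_lt(max(abs(ev$gradient)), 1e-3)
})

test_that("analytic gradient matches central finite differences (frozen grid)", {
  fx <- t1_fixture()
  obj <- hier_objective(fx$ds$model, fx$ds$data, fx$cfg,
                        rtol = 1e-11, atol = 1e-13,
                        fixed_knots = fx$fixed_knots)
  set.seed(31)
  for (r in 1:4) {
    th <- c(runif(2, -0.5, 0.8), runif(2, -1, 1))
    ev <- evaluate_objective(obj, th)
    h <- 1e-6
    g_fd <- vapply(1:4, function(j) {
      tp <- th; tp[j] <- th[j] + h
      tm <- th; tm[j] <- th[j] - h
      (evaluate_objective(obj, tp, with_gradient = FALSE)$J -
         evaluate_objective(obj, tm, with_gradient = FALSE)$J) / (2 * h)
    }, numeric(1))
    rel <- abs(ev$gradient - g_fd) / pmax(abs(g_fd) + abs(ev$gradient), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("gradient agrees with directional finite differences in random directions", {
  fx <- t1_fixture()
  obj <- hier_objective(fx$ds$model, fx$ds$data, fx$cfg,
                        rtol = 1e-11, atol = 1e-13,
                        fixed_knots = fx$fixed_knots)
  th <- fx$pr$theta_true_log10 + c(0.1, -0.1, 0.2, -0.2)
  ev <- evaluate_objective(obj, th)
  set.seed(32)
  h <- 1e-6
  for (r in 1:10) {
    d <- rnorm(4); d <- d / sqrt(sum(d^2))
    fd <- (evaluate_objective(obj, th + h * d, with_gradient = FALSE)$J -
             evaluate_objective(obj, th - h * d, with_gradient = FALSE)$J) /
      (2 * h)
    an <- sum(ev$gradient * d)
    expect_lt(abs(an - fd) / max(abs(fd), abs(an), 1e-8), 1e-4)
  }
})

test_that("perturbing the inner optimum changes J only at second order", {
  fx <- t1_fixture()
  obj <- hier_objective(fx$ds$model, fx$ds$data, fx$cfg,
                        fixed_knots = fx$fixed_knots)
  th <- fx$pr$theta_true_log10
  ev <- evaluate_objective(obj, th, with_gradient = FALSE)
  sol <- ev$inner$active_fraction
  layout <- joint_layout(obj)
  v_star <- stack_joint(obj, th, ev$inner, layout)
  ## feasible direction: keep increments nonnegative
  set.seed(33)
  d <- abs(rnorm(length(sol$psi)))
  d <- d / sqrt(sum(d^2))
  deltas <- 10^seq(-5, -2, length.out = 7)
  dJ <- vapply(deltas, function(del) {
    v <- v_star
    idx <- layout$slots$active_fraction$start +
      seq_along(sol$psi) - 1L
    v[idx] <- v[idx] + del * d
    joint_objective(obj, v, layout, with_gradient = FALSE)$J - ev$J
  }, numeric(1))
  expect_true(all(dJ > 0))
  slope <- coef(lm(log(dJ) ~ log(deltas)))[2]
  expect_gte(slope, 1.9)
})

test_that("joint value at the inner optimum equals the hierarchical value", {
  fx <- t1_fixture()
  obj <- hier_objective(fx$ds$model, fx$ds$data, fx$cfg,
                        fixed_knots = fx$fixed_knots)
  th <- fx$pr$theta_true_log10 + c(-0.05, 0.08, 0, 0)
  ev <- evaluate_objective(obj, th)
  layout <- joint_layout(obj)
  v <- stack_joint(obj, th, ev$inner, layout)
  jv <- joint_objective(obj, v, layout)
  expect_equal(jv$J, ev$J, tolerance = 1e-12)
  ## KKT in the psi block: gradient ~0 on inactive bounds, >= 0 at zero
  idx <- layout$slots$active_fraction$start + seq_along(ev$inner$active_fraction$psi) - 1L
  gpsi <- jv$gradient[idx]
  active <- ev$inner$active_fraction$psi <= 1e-12
  expect_true(all(gpsi[active] >= -1e-5))
  if (any(!active)) expect_lt(max(abs(gpsi[!active])), 1e-5)
  ## theta gradient agrees with the hierarchical (envelope) gradient
  expect_equal(jv$gradient[1:4], ev$gradient, tolerance = 1e-8)
})

test_that("hierarchical J(theta) lower-bounds the joint J(theta, psi) over random psi", {
  fx <- t1_fixture()
  obj <- hier_objective(fx$ds$model, fx$ds$data, fx$cfg,
                        fixed_knots = fx$fixed_knots)
  th <- fx$pr$theta_true_log10
  ev <- evaluate_objective(obj, th, with_gradient = FALSE)
  layout <- joint_layout(obj)
  set.seed(34)
  for (r in 1:25) {
    v <- stack_joint(obj, th, ev$inner, layout)
    idx <- layout$slots$active_fraction$start +
      seq_along(ev$inner$active_fraction$psi) - 1L
    v[idx] <- runif(length(idx), 0, 0.5)
    expect_gte(joint_objective(obj, v, layout, with_gradient = FALSE)$J,
               ev$J - 1e-10)
  }
})

test_that("failed simulations yield an infinite objective, not an error", {
  spec <- ode_model_spec("x", "k", c(x = "k*x^2"), c(x = "1"), c(y = "x"),
                         lower = -2, upper = 4)
  data <- data.frame(observableId = "y", time = c(1, 5, 10),
                     measurement = c(1, 2, 3))
  obj <- hier_objective(spec, data, list(observable_config("y", "relative")))
  ev <- evaluate_objective(obj, 3.5)   # k ~ 3000: finite-time blow-up
  expect_false(ev$success)
  expect_identical(ev$J, Inf)
})
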