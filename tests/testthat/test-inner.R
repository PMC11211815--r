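test_that("relative inner solution recovers exact affine data", {
  y <- c(0.1, 0.4, 0.9, 1.3, 2)
  cfg <- observable_config("o", "relative")
  sol <- solve_relative(y, 2 * y + 1, cfg)
  expect_equal(unname(sol$psi["a"]), 2, tolerance = 1e-12)
  expect_equal(unname(sol$psi["b"]), 1, tolerance = 1e-12)
  expect_equal(sol$sigma, 1e-10)  # floored on perfect data

  const <- solve_relative(y, rep(3.3, 5), cfg)
  expect_equal(unname(const$psi["a"]), 0)
  expect_equal(unname(const$psi["b"]), 3.3)
})

test_that("degenerate simulation (zero variance) is flagged non-identifiable", {
  cfg <- observable_config("o", "relative")
  sol <- solve_relative(rep(2, 4), c(1, 2, 3, 4), cfg)
  expect_true("nonidentifiable_scaling" %in% sol$flags)
  expect_equal(unname(sol$psi["a"]), 0)
  expect_equal(unname(sol$psi["b"]), 2.5)
})

test_that("relative closed form matches a numerical minimizer of the inner NLL", {
  set.seed(21)
  for (r in 1:5) {
    y <- runif(8, 0, 3)
    z <- 1.5 * y - 0.3 + rnorm(8, 0, 0.2)
    cfg <- observable_config("o", "relative")
    sol <- solve_relative(y, z, cfg)
    nll <- function(p) {
      s <- exp(p[3])
      sum(0.5 * log(2 * pi * s^2) + (p[1] * y + p[2] - z)^2 / (2 * s^2))
    }
    num <- optim(c(1, 0, log(0.1)), nll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000))
    expect_equal(unname(sol$psi["a"]), num$par[1], tolerance = 1e-5)
    expect_equal(unname(sol$psi["b"]), num$par[2], tolerance = 1e-5)
    expect_equal(sol$sigma, exp(num$par[3]), tolerance = 1e-5)
    expect_equal(sol$J, num$value, tolerance = 1e-6)
  }
})

test_that("noiseless identity data with lambda = 0 recovers equal increments", {
  y <- seq(0.1, 2, length.out = 12)
  cfg <- observable_config("o", "nonlinear_monotone", lambda = 0, margin = 0)
  sol <- solve_spline_inner(y, y, cfg)
  dc <- sol$mapping$dc
  expect_lt(max(abs(sol$psi - dc)), 1e-8)
  expect_lt(max(abs(sol$residuals)), 1e-8)
  expect_equal(sol$sigma, 1e-10)
  ## J at the sigma floor is the pure Gaussian normalization constant
  expect_equal(sol$J, length(y) * 0.5 * log(2 * pi * 1e-20), tolerance = 1e-6)
})

test_that("all-zero measurements give a zero spline", {
  y <- seq(0.2, 1, length.out = 6)
  cfg <- observable_config("o", "nonlinear_monotone", lambda = 0, n_knots = 4)
  sol <- solve_spline_inner(y, rep(0, 6), cfg)
  expect_equal(unname(sol$psi), rep(0, 4))
  ## more knots than data points draws a warning
  cfg8 <- observable_config("o", "nonlinear_monotone", lambda = 0, n_knots = 8)
  expect_warning(solve_spline_inner(y, rep(0, 6), cfg8), "underdetermined")
})

test_that("tiny spline instances match a brute-force grid search with polish", {
  set.seed(22)
  for (r in 1:3) {
    y <- sort(runif(5, 0.1, 1))
    z <- sqrt(y) + rnorm(5, 0, 0.05)
    sigma <- 0.05
    cfg <- observable_config("o", "nonlinear_monotone", noise_mode = "known",
                             known_sigma = sigma, n_knots = 3, margin = 0.1,
                             lambda = 1e-2)
    sol <- solve_spline_inner(y, z, cfg)
    knots <- sol$mapping$knots
    B <- spline_basis_matrix(knots, y)
    obj <- function(xi) {
      r_ <- as.numeric(B %*% xi) - z
      sum(0.5 * log(2 * pi * sigma^2) + r_^2 / (2 * sigma^2)) +
        regularization_penalty(xi, 1e-2)$value
    }
    ## coarse exhaustive search over [0, 2]^3, then local polish
    grid <- seq(0, 2, by = 0.05)
    best <- NULL; bestv <- Inf
    for (x1 in grid) for (x2 in grid) for (x3 in grid) {
      v <- obj(c(x1, x2, x3))
      if (v < bestv) { bestv <- v; best <- c(x1, x2, x3) }
    }
    pol <- optim(best, obj, method = "L-BFGS-B", lower = 0, upper = 4,
                 control = list(factr = 1e1))
    expect_equal(sol$J, pol$value, tolerance = 1e-6)
    expect_lt(max(abs(sol$psi - pol$par)), 1e-3)
  }
})

test_that("KKT conditions hold at the spline inner optimum", {
  set.seed(23)
  for (r in 1:10) {
    y <- sort(runif(12, 0.05, 2))
    z <- 0.8 * (1 - exp(-y / 0.4)) + rnorm(12, 0, 0.03)
    cfg <- observable_config("o", "nonlinear_monotone", noise_mode = "known",
                             known_sigma = 0.03, lambda = 1e-2)
    sol <- solve_spline_inner(y, z, cfg)
    B <- spline_basis_matrix(sol$mapping$knots, y)
    g <- as.numeric(crossprod(B, sol$residuals)) / 0.03^2 +
      regularization_penalty(sol$psi, 1e-2)$gradient
    at_bound <- sol$psi <= 1e-12
    expect_true(all(g[at_bound] >= -1e-6))
    if (any(!at_bound)) expect_lt(max(abs(g[!at_bound])), 1e-6)
  }
})

test_that("inner objective is convex and the solution beats random feasible points", {
  set.seed(24)
  y <- sort(runif(10, 0.1, 1.5))
  z <- y^2 + rnorm(10, 0, 0.05)
  cfg <- observable_config("o", "nonlinear_monotone", noise_mode = "known",
                           known_sigma = 0.05, lambda = 1e-2)
  sol <- solve_spline_inner(y, z, cfg)
  B <- spline_basis_matrix(sol$mapping$knots, y)
  obj <- function(xi) {
    r_ <- as.numeric(B %*% xi) - z
    sum(0.5 * log(2 * pi * 0.05^2) + r_^2 / (2 * 0.05^2)) +
      regularization_penalty(xi, 1e-2)$value
  }
  n <- length(sol$psi)
  for (r in 1:100) {
    xi1 <- runif(n, 0, 2); xi2 <- runif(n, 0, 2); a <- runif(1)
    expect_lte(obj(a * xi1 + (1 - a) * xi2),
               max(obj(xi1), obj(xi2)) + 1e-10)
  }
  draws <- replicate(1000, obj(runif(n, 0, 2)))
  expect_lte(obj(sol$psi), min(draws))
})

test_that("spline fit nests and beats the best origin-affine fit for lambda = 0", {
  set.seed(25)
  y <- sort(runif(15, 0.1, 2))
  z <- 1.3 * y / (0.5 + y) + rnorm(15, 0, 0.02)
  cfg <- observable_config("o", "nonlinear_monotone", noise_mode = "known",
                           known_sigma = 0.02, lambda = 0)
  sol <- solve_spline_inner(y, z, cfg)
  a_star <- sum(y * z) / sum(y^2)   # best scaling through the origin
  J_affine <- sum(0.5 * log(2 * pi * 0.02^2) +
                    (a_star * y - z)^2 / (2 * 0.02^2))
  expect_lte(sol$J, J_affine + 1e-9)
})

test_that("estimated sigma is the RMS residual", {
  set.seed(26)
  y <- sort(runif(10, 0.1, 2))
  z <- y + rnorm(10, 0, 0.1)
  cfg <- observable_config("o", "nonlinear_monotone", lambda = 0)
  sol <- solve_spline_inner(y, z, cfg)
  expect_equal(sol$sigma, sqrt(mean(sol$residuals^2)), tolerance = 1e-12)
  rcfg <- observable_config("o", "relative")
  rsol <- solve_relative(y, z, rcfg)
  expect_equal(rsol$sigma, sqrt(mean(rsol$residuals^2)), tolerance = 1e-12)
})

test_that("inner problems are independent across observables and J is additive", {
  ds <- cascade_dataset(seed = 3)
  sim <- simulate_model(ds$model, ds$theta_true, ds$times)
  configs <- list(
    observable_config("obs_AC", "quantitative"),
    observable_config("obs_B", "relative"),
    observable_config("obs_BC", "nonlinear_monotone"))
  sols <- solve_inner_all(sim, ds$data, configs)
  expect_setequal(names(sols), c("obs_AC", "obs_B", "obs_BC"))
  J_total <- sum(vapply(sols, function(s) s$J, numeric(1)))

  ## permuting observable order (configs and rows) leaves results unchanged
  perm <- ds$data[order(-as.integer(factor(ds$data$observableId))), ]
  sols2 <- solve_inner_all(sim, perm, rev(configs))
  for (oid in names(sols))
    expect_equal(sols2[[oid]]$J, sols[[oid]]$J, tolerance = 1e-12)

  ## joint numerical minimization over all observable parameters agrees
  obj_joint <- function(p) {
    a <- p[1]; b <- p[2]; xi <- pmax(p[3:10], 0)
    JB <- {
      yB <- sim$observables["obs_B", ]
      zB <- ds$data$measurement[ds$data$observableId == "obs_B"]
      r <- a * yB + b - zB
      s2 <- max(mean(r^2), 1e-20)
      sum(0.5 * log(2 * pi * s2) + r^2 / (2 * s2))
    }
    JC <- {
      yC <- sim$observables["obs_BC", ]
      zC <- ds$data$measurement[ds$data$observableId == "obs_BC"]
      B <- spline_basis_matrix(sols$obs_BC$mapping$knots, yC)
      r <- as.numeric(B %*% xi) - zC
      s2 <- max(mean(r^2), 1e-20)
      sum(0.5 * log(2 * pi * s2) + r^2 / (2 * s2)) +
        regularization_penalty(xi, 1e-2)$value
    }
    JB + JC
  }
  p0 <- c(sols$obs_B$psi, sols$obs_BC$psi)
  num <- optim(p0, obj_joint, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_lte(sols$obs_B$J + sols$obs_BC$J, num$value + 1e-6)
})
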