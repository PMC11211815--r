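## Memoizing wrapper so that optim's separate fn/gr calls at the same
## point cost a single objective evaluation.
memo_objective <- function(obj) {
  last <- new.env(parent = emptyenv())
  last$theta <- NULL
  get_eval <- function(theta) {
    if (!is.null(last$theta) && identical(last$theta, theta))
      return(last$ev)
    ev <- evaluate_objective(obj, theta, with_gradient = TRUE)
    last$theta <- theta
    last$ev <- ev
    ev
  }
  list(
    fn = function(theta) {
      J <- get_eval(theta)$J
      if (!is.finite(J)) 1e12 else J
    },
    gr = function(theta) {
      ev <- get_eval(theta)
      if (!ev$success || is.null(ev$gradient)) rep(0, length(theta))
      else ev$gradient
    }
  )
}

#' Latin-hypercube start points over the parameter bounds
#'
#' @param obj a \code{hier_objective}.
#' @param n number of starts.
#' @param seed RNG seed.
#' @return n x n_theta matrix of start points on the estimation scale.
#' @export
sample_startpoints <- function(obj, n, seed) {
  lo <- obj$bounds$lower; hi <- obj$bounds$upper
  set.seed(seed)
  u <- lhs::randomLHS(n, length(lo))
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

#' Multi-start maximum-likelihood estimation
#'
#' Draws start points by Latin hypercube over the (log10) bounds and runs
#' a bounded local optimization from each. The default mode consumes the
#' analytic hierarchical gradient (L-BFGS-B); the gradient-free mode uses
#' a bounded Nelder-Mead simplex search as the derivative-free baseline.
#'
#' @param obj a \code{hier_objective}.
#' @param n_starts number of local optimizations.
#' @param seed RNG seed for the start points.
#' @param mode \code{"gradient"} or \code{"gradient_free"}.
#' @param startpoints optional matrix of start points overriding the
#'   Latin-hypercube draw (rows = starts).
#' @param maxit iteration cap per start.
#' @param reltol relative convergence tolerance (gradient-free mode).
#' @return a \code{fit_result}: per-start table, best \code{theta_star}
#'   and \code{J_star}, inner solutions at the optimum, seed and settings.
#' @export
multistart_fit <- function(obj, n_starts = 50, seed = 1,
                           mode = c("gradient", "gradient_free"),
                           startpoints = NULL, maxit = 500, reltol = 1e-10) {
  mode <- match.arg(mode)
  assert_that(n_starts >= 1, "n_starts must be >= 1")
  lo <- obj$bounds$lower; hi <- obj$bounds$upper
  if (is.null(startpoints)) startpoints <- sample_startpoints(obj, n_starts, seed)
  startpoints <- as.matrix(startpoints)
  assert_that(ncol(startpoints) == length(lo), "startpoint dimension mismatch")
  n_starts <- nrow(startpoints)

  mo <- memo_objective(obj)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th0 <- startpoints[s, ]
    n0 <- n_evaluations(obj)
    res <- if (mode == "gradient") {
      r <- NULL
      for (round in 1:3) {
        rr <- tryCatch(stats::optim(if (is.null(r)) th0 else r$par,
                                    fn = mo$fn, gr = mo$gr,
                                    method = "L-BFGS-B",
                                    lower = lo, upper = hi,
                                    control = list(maxit = maxit,
                                                   factr = 1e1)),
                       error = function(e) NULL)
        if (is.null(rr)) break
        if (!is.null(r) && r$value - rr$value < 1e-8) { r <- rr; break }
        r <- rr
      }
      r
    } else {
      ## bounded derivative-free search: clamp to the box inside the wrapper
      fn_clamped <- function(th) mo$fn(pmin(pmax(th, lo), hi))
      r <- tryCatch(stats::optim(th0, fn = fn_clamped, method = "Nelder-Mead",
                                 control = list(maxit = maxit * 20,
                                                reltol = reltol)),
                    error = function(e) NULL)
      if (!is.null(r)) r$par <- pmin(pmax(r$par, lo), hi)
      r
    }
    n1 <- n_evaluations(obj)
    if (is.null(res)) {
      starts[[s]] <- list(theta0 = th0, theta = rep(NA_real_, length(lo)),
                          J = Inf, grad_norm = NA_real_, n_evals = n1 - n0,
                          converged_opt = FALSE, success = FALSE)
      next
    }
    ev <- evaluate_objective(obj, res$par, with_gradient = TRUE)
    gn <- if (ev$success) sqrt(sum(ev$gradient^2)) else NA_real_
    starts[[s]] <- list(theta0 = th0, theta = res$par, J = ev$J,
                        grad_norm = gn, n_evals = n1 - n0,
                        converged_opt = res$convergence == 0,
                        success = is.finite(ev$J))
  }
  Js <- vapply(starts, function(x) x$J, numeric(1))
  if (all(!is.finite(Js)))
    stop_sq("all %d starts failed; check model and data", n_starts)
  ord <- order(Js)
  starts <- starts[ord]
  best <- starts[[1]]
  best_ev <- evaluate_objective(obj, best$theta, with_gradient = FALSE)
  structure(list(starts = starts, theta_star = best$theta,
                 J_star = best$J, inner_star = best_ev$inner,
                 seed = seed, mode = mode, n_starts = n_starts,
                 parameter_names = obj$model$parameter_names),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("multi-start fit (%s mode): %d starts, J* = %.6g\n",
              x$mode, x$n_starts, x$J_star))
  th <- x$theta_star
  cat("theta* (estimation scale): ",
      paste(sprintf("%s=%.4g", x$parameter_names, th), collapse = ", "), "\n")
  invisible(x)
}

#' Multi-start estimation in the full (theta, psi) space
#'
#' The non-hierarchical baseline: the same likelihood optimized jointly
#' over mechanistic and observable parameters with bound constraints
#' (increments >= 0). Spline observables require a fixed knot grid; if
#' the objective was built without one, a grid is derived once from a
#' simulation at the first start point. The psi block of each start is
#' initialized at the inner optimum for that start's theta.
#'
#' @inheritParams multistart_fit
#' @return a \code{fit_result} whose \code{theta_star} is the mechanistic
#'   block of the best joint optimum (per-start \code{theta} likewise).
#' @export
joint_multistart_fit <- function(obj, n_starts = 50, seed = 1,
                                 startpoints = NULL, maxit = 500) {
  lo <- obj$bounds$lower; hi <- obj$bounds$upper
  if (is.null(startpoints)) startpoints <- sample_startpoints(obj, n_starts, seed)
  startpoints <- as.matrix(startpoints)
  n_starts <- nrow(startpoints)
  np <- obj$model$np

  spline_ids <- names(Filter(function(cf)
    cf$mapping_class == "nonlinear_monotone", obj$configs))
  spline_ids <- intersect(spline_ids, unique(obj$data$observableId))
  if (length(spline_ids) && is.null(obj$fixed_knots)) {
    ev0 <- evaluate_objective(obj, startpoints[1, ], with_gradient = FALSE)
    assert_that(ev0$success, "cannot derive a knot grid: start simulation failed")
    obj$fixed_knots <- lapply(ev0$inner[spline_ids],
                              function(sol) sol$mapping$knots)
    names(obj$fixed_knots) <- spline_ids
  }
  layout <- joint_layout(obj)

  last <- new.env(parent = emptyenv()); last$v <- NULL
  get_eval <- function(v) {
    if (!is.null(last$v) && identical(last$v, v)) return(last$ev)
    ev <- joint_objective(obj, v, layout, with_gradient = TRUE)
    last$v <- v; last$ev <- ev
    ev
  }
  fn <- function(v) { J <- get_eval(v)$J; if (is.finite(J)) J else 1e12 }
  gr <- function(v) {
    ev <- get_eval(v)
    if (!ev$success || is.null(ev$gradient)) rep(0, length(v)) else ev$gradient
  }

  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th0 <- startpoints[s, ]
    ev <- evaluate_objective(obj, th0, with_gradient = FALSE)
    v0 <- if (ev$success) stack_joint(obj, th0, ev$inner, layout)
          else c(th0, rep(1, layout$n_total - np))
    n0 <- n_evaluations(obj)
    ## L-BFGS-B with restart polish: re-invoking from the terminal point
    ## resets the Hessian memory and escapes premature stalls, which are
    ## common in the high-dimensional joint space
    res <- NULL
    for (round in 1:4) {
      vstart <- if (is.null(res)) v0 else res$par
      r <- tryCatch(stats::optim(vstart, fn = fn, gr = gr, method = "L-BFGS-B",
                                 lower = layout$lower, upper = layout$upper,
                                 control = list(maxit = maxit, factr = 1e1)),
                    error = function(e) NULL)
      if (is.null(r)) break
      if (!is.null(res) && res$value - r$value < 1e-8) { res <- r; break }
      res <- r
    }
    n1 <- n_evaluations(obj)
    if (is.null(res)) {
      starts[[s]] <- list(theta0 = th0, theta = rep(NA_real_, np), J = Inf,
                          grad_norm = NA_real_, n_evals = n1 - n0,
                          converged_opt = FALSE, success = FALSE)
      next
    }
    evf <- joint_objective(obj, res$par, layout, with_gradient = TRUE)
    starts[[s]] <- list(theta0 = th0, theta = res$par[seq_len(np)],
                        v = res$par, J = evf$J,
                        grad_norm = if (evf$success)
                          sqrt(sum(evf$gradient^2)) else NA_real_,
                        n_evals = n1 - n0,
                        converged_opt = res$convergence == 0,
                        success = is.finite(evf$J))
  }
  Js <- vapply(starts, function(x) x$J, numeric(1))
  if (all(!is.finite(Js)))
    stop_sq("all %d joint starts failed", n_starts)
  starts <- starts[order(Js)]
  best <- starts[[1]]
  best_ev <- evaluate_objective(obj, best$theta, with_gradient = FALSE)
  structure(list(starts = starts, theta_star = best$theta, J_star = best$J,
                 inner_star = best_ev$inner, seed = seed, mode = "joint",
                 n_starts = n_starts,
                 parameter_names = obj$model$parameter_names,
                 fixed_knots = obj$fixed_knots),
            class = "fit_result")
}

#' Likelihood-ratio statistic
#'
#' Lambda(theta) = 2 * (J(theta) - J(theta*)), clipped at zero.
#'
#' @param J_at_theta objective value at the tested parameters.
#' @param J_star objective value at the maximum-likelihood estimate.
#' @param tol consistency slack: \code{J_at_theta} below
#'   \code{J_star - tol} indicates an inconsistent reference.
#' @export
likelihood_ratio_statistic <- function(J_at_theta, J_star, tol = 1e-6) {
  assert_that(is.finite(J_star), "J_star must be finite")
  if (is.finite(J_at_theta) && J_at_theta < J_star - tol)
    stop_sq("J(theta) = %g is below the reference optimum %g: inconsistent J_star",
            J_at_theta, J_star)
  max(0, 2 * (J_at_theta - J_star))
}

#' Chi-square threshold of the likelihood-ratio confidence region
#'
#' @param alpha confidence level in (0, 1), e.g. 0.95.
#' @param df degrees of freedom (number of mechanistic parameters).
#' @export
confidence_threshold <- function(alpha, df) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  stats::qchisq(alpha, df = df)
}

#' Test whether a parameter vector lies in the confidence region
#'
#' @param J_at_theta objective at theta.
#' @param J_star reference optimum.
#' @param alpha confidence level.
#' @param df degrees of freedom.
#' @return logical.
#' @export
in_confidence_region <- function(J_at_theta, J_star, alpha = 0.95, df) {
  likelihood_ratio_statistic(J_at_theta, J_star) <=
    confidence_threshold(alpha, df)
}

#' Classify which starts converged to the confidence region
#'
#' A start counts as converged when its final likelihood-ratio statistic
#' relative to the best start does not exceed the chi-square threshold
#' with df = number of mechanistic parameters.
#'
#' @param fit a \code{fit_result}.
#' @param alpha confidence level (default 0.95).
#' @return logical vector, one flag per (sorted) start.
#' @export
classify_converged <- function(fit, alpha = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  df <- length(fit$theta_star)
  thr <- confidence_threshold(alpha, df)
  vapply(fit$starts, function(s) {
    is.finite(s$J) && 2 * max(0, s$J - fit$J_star) <= thr
  }, logical(1))
}

#' Classify the shape of a fitted measurement mapping
#'
#' Decision rule on the fitted spline: the data can be deemed
#' quantitative (mapping is the identity within tolerance over the covered
#' range), relative (mapping is affine within tolerance), censored-like
#' (a run of two or more zero increments abuts either end of the grid,
#' i.e. a detection floor or saturation plateau), or genuinely nonlinear.
#'
#' @param mapping a \code{spline_mapping}.
#' @param range_x data-covered input range (default the full grid).
#' @param tol_identity absolute tolerance for |s(x) - x|.
#' @param tol_affine absolute tolerance for the residual of an affine fit
#'   to the knot heights.
#' @param tol_zero increments at or below this count as zero.
#' @return one of \code{"quantitative"}, \code{"relative"},
#'   \code{"censored-like"}, \code{"nonlinear"}.
#' @export
classify_mapping <- function(mapping, range_x = NULL,
                             tol_identity = 0.05, tol_affine = 0.05,
                             tol_zero = 1e-8) {
  stopifnot(inherits(mapping, "spline_mapping"))
  if (is.null(range_x)) range_x <- c(0, max(mapping$knots))
  xs <- seq(range_x[1], range_x[2], length.out = 201)
  sx <- eval_spline(mapping, xs)
  if (max(abs(sx - xs)) <= tol_identity) return("quantitative")
  heights <- c(0, cumsum(mapping$increments))
  bases <- c(0, mapping$knots)
  fit <- stats::lm.fit(cbind(1, bases), heights)
  if (max(abs(fit$residuals)) <= tol_affine) return("relative")
  z <- mapping$increments <= tol_zero
  r <- rle(z)
  lead0 <- if (r$values[1]) r$lengths[1] else 0L
  trail0 <- if (r$values[length(r$values)]) r$lengths[length(r$values)] else 0L
  if (max(lead0, trail0) >= 2L) return("censored-like")
  "nonlinear"
}
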