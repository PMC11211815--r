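#' Hierarchical negative log-likelihood objective
#'
#' Builds the nested objective J(theta) = sum_i J_i(theta, psi_i*(theta)):
#' for each trial mechanistic parameter vector, the model is simulated and
#' every observable's mapping/noise parameters psi_i are profiled out in an
#' inner problem (closed form for relative observables, convex nonnegative
#' least squares for spline observables). The outer gradient is analytic:
#' because the inner optimum is stationary (envelope property), only the
#' explicit dependence through the simulated observables contributes,
#' \deqn{\nabla_\theta J = \sum_{i,k} \frac{m_{ik} - \tilde z_{ik}}{\sigma_i^2}
#'   \, g_i'(y_{ik}) \, \frac{\partial y_{ik}}{\partial \theta}}
#' with m the mapped simulation and g_i' the local mapping slope (1, a_i,
#' or the spline slope). Reported on the estimation (log10 by default)
#' scale.
#'
#' By default the spline knot grid is recomputed from the current
#' simulation at every evaluation so the spline always covers the
#' simulated range; supply \code{fixed_knots} (named list per spline
#' observable) for a strictly smooth objective, e.g. when checking
#' gradients by finite differences or when running joint optimization.
#'
#' @param model an \code{ode_model_spec} or \code{compiled_model}.
#' @param data measurement data frame (\code{observableId}, \code{time},
#'   \code{measurement}, optional \code{noiseValue}).
#' @param configs list of \code{\link{observable_config}}s.
#' @param rtol,atol integrator tolerances.
#' @param fixed_knots optional named list of fixed knot grids.
#' @param trace logical; record J at every evaluation (for efficiency
#'   accounting).
#' @return an object of class \code{hier_objective}.
#' @export
hier_objective <- function(model, data, configs, rtol = 1e-8, atol = 1e-10,
                           fixed_knots = NULL, trace = FALSE) {
  cm <- as_compiled(model)
  assert_that(all(c("observableId", "time", "measurement") %in% names(data)),
              "data needs columns observableId, time, measurement")
  assert_that(all(is.finite(data$measurement)), "measurements must be finite")
  cfg_ids <- vapply(configs, function(cf) cf$observable_id, character(1))
  names(configs) <- cfg_ids
  miss <- setdiff(unique(data$observableId), cfg_ids)
  if (length(miss))
    stop_sq("no observable_config for measured observable '%s'", miss[[1]])
  bad <- setdiff(unique(data$observableId), cm$observable_names)
  if (length(bad))
    stop_sq("measured observable '%s' is not a model observable", bad[[1]])
  ## stable ordering by (observable, time)
  data <- data[order(data$observableId, data$time), , drop = FALSE]
  bounds <- cm$spec$bounds
  counter <- new.env(parent = emptyenv())
  counter$n_evals <- 0L
  counter$trace <- numeric(0)
  structure(list(model = cm, data = data, configs = configs,
                 times = sort(unique(data$time)),
                 rtol = rtol, atol = atol,
                 fixed_knots = fixed_knots,
                 bounds = bounds,
                 do_trace = trace,
                 counter = counter),
            class = "hier_objective")
}

#' Map parameters between estimation scale and natural scale
#' @keywords internal
theta_to_natural <- function(obj, theta) {
  s <- obj$bounds$scale
  ifelse(s == "log10", 10^theta, theta)
}

#' Number of objective evaluations performed so far
#' @param obj a \code{hier_objective}.
#' @export
n_evaluations <- function(obj) obj$counter$n_evals

#' Reset the evaluation counter and trace
#' @param obj a \code{hier_objective}.
#' @export
reset_counter <- function(obj) {
  obj$counter$n_evals <- 0L
  obj$counter$trace <- numeric(0)
  invisible(obj)
}

#' Evaluation trace (J per objective evaluation)
#' @param obj a \code{hier_objective}.
#' @export
evaluation_trace <- function(obj) obj$counter$trace

record_eval <- function(obj, J) {
  obj$counter$n_evals <- obj$counter$n_evals + 1L
  if (obj$do_trace) obj$counter$trace <- c(obj$counter$trace, J)
  invisible(NULL)
}

#' Evaluate the hierarchical objective (and analytic gradient)
#'
#' @param obj a \code{hier_objective}.
#' @param theta parameter vector on the estimation scale.
#' @param with_gradient compute the analytic gradient as well.
#' @return list with \code{J}, \code{gradient} (or NULL), \code{inner}
#'   (per-observable \code{inner_solution}s), \code{sim}, \code{success}.
#' @export
evaluate_objective <- function(obj, theta, with_gradient = TRUE) {
  stopifnot(inherits(obj, "hier_objective"))
  theta_nat <- theta_to_natural(obj, theta)
  sim <- simulate_model(obj$model, theta_nat, obj$times,
                        with_sensitivities = with_gradient,
                        rtol = obj$rtol, atol = obj$atol)
  if (!sim$success) {
    record_eval(obj, Inf)
    return(list(J = Inf, gradient = NULL, inner = NULL, sim = sim,
                success = FALSE))
  }
  inner <- tryCatch(
    solve_inner_all(sim, obj$data, obj$configs, obj$fixed_knots),
    error = function(e) e)
  if (inherits(inner, "error")) {
    record_eval(obj, Inf)
    return(list(J = Inf, gradient = NULL, inner = NULL, sim = sim,
                success = FALSE, message = conditionMessage(inner)))
  }
  J <- sum(vapply(inner, function(s) s$J, numeric(1)))
  grad <- NULL
  if (with_gradient) {
    np <- obj$model$np
    g_nat <- numeric(np)
    for (sol in inner) {
      oid <- sol$observable_id
      io <- match(oid, obj$model$observable_names)
      dy <- sim$sensitivities[io, sol$time_index, , drop = FALSE]
      dy <- matrix(dy, nrow = length(sol$time_index), ncol = np)
      wres <- sol$residuals / sol$sigma^2 * sol$slope
      g_nat <- g_nat + as.numeric(crossprod(dy, wres))
      if (sol$mapping_class == "nonlinear_monotone" &&
          is.null(obj$fixed_knots[[oid]])) {
        ## adaptive grid: the knot spacing dc = (1+margin)*max(y)/n_knots
        ## moves with theta; chain that dependence through the argmax
        ## point (the envelope takes care of xi*, which re-optimizes with
        ## the grid). ds/ddc = -slope_k * y_k / dc inside the grid, 0
        ## beyond it.
        cfg <- obj$configs[[oid]]
        dc <- sol$mapping$dc
        dJd_dc <- sum(sol$residuals / sol$sigma^2 *
                        (-sol$slope * sol$y / dc))
        kmax <- which.max(sol$y)
        g_nat <- g_nat + dJd_dc * (1 + cfg$margin) / cfg$n_knots *
          dy[kmax, ]
      }
    }
    chain <- ifelse(obj$bounds$scale == "log10", log(10) * theta_nat, 1)
    grad <- g_nat * chain
  }
  record_eval(obj, J)
  list(J = J, gradient = grad, inner = inner, sim = sim, success = TRUE)
}

## ---------------------------------------------------------------------
## Joint (non-hierarchical) objective: same likelihood optimized in the
## full (theta, psi) space. Noise SDs are profiled analytically in both
## formulations so that joint and hierarchical optima are on the same
## scale. Requires fixed knot grids for spline observables so that the
## increment parameters have a stable meaning across iterations.
## ---------------------------------------------------------------------

#' Layout of the stacked (theta, psi) vector for joint optimization
#'
#' @param obj a \code{hier_objective} (with \code{fixed_knots} set for
#'   every spline observable).
#' @return list describing slots: per-observable psi offsets, lengths,
#'   lower/upper bounds for the stacked vector.
#' @export
joint_layout <- function(obj) {
  ids <- names(obj$configs)
  measured <- intersect(unique(obj$data$observableId), ids)
  off <- obj$model$np
  slots <- list()
  lower <- obj$bounds$lower; upper <- obj$bounds$upper
  for (oid in measured) {
    cfg <- obj$configs[[oid]]
    len <- switch(cfg$mapping_class,
                  quantitative = 0L,
                  relative = 2L,
                  nonlinear_monotone = {
                    if (is.null(obj$fixed_knots[[oid]]))
                      stop_sq("joint optimization needs fixed_knots for spline observable '%s'", oid)
                    length(obj$fixed_knots[[oid]])
                  })
    if (len > 0) {
      slots[[oid]] <- list(start = off + 1L, length = len,
                           class = cfg$mapping_class)
      lo <- if (cfg$mapping_class == "relative") c(-1e4, -1e4) else rep(0, len)
      hi <- rep(1e4, len)
      lower <- c(lower, lo); upper <- c(upper, hi)
      off <- off + len
    } else {
      slots[[oid]] <- list(start = NA_integer_, length = 0L,
                           class = cfg$mapping_class)
    }
  }
  list(slots = slots, n_total = off, lower = lower, upper = upper,
       measured = measured)
}

#' Joint objective value and gradient at a stacked (theta, psi) point
#'
#' Same Gaussian likelihood as the hierarchical objective, with mapping
#' parameters supplied rather than profiled (noise SDs are still profiled
#' analytically, or taken as known). Used as the non-hierarchical
#' optimization baseline and as an oracle for inner-optimality checks.
#'
#' @param obj a \code{hier_objective} with fixed knot grids.
#' @param v stacked vector: theta (estimation scale) followed by each
#'   measured observable's psi in \code{joint_layout} order.
#' @param layout result of \code{\link{joint_layout}} (recomputed if NULL).
#' @param with_gradient compute the full-space analytic gradient.
#' @return list with \code{J}, \code{gradient}, \code{success}.
#' @export
joint_objective <- function(obj, v, layout = NULL, with_gradient = TRUE) {
  if (is.null(layout)) layout <- joint_layout(obj)
  np <- obj$model$np
  theta <- v[seq_len(np)]
  theta_nat <- theta_to_natural(obj, theta)
  sim <- simulate_model(obj$model, theta_nat, obj$times,
                        with_sensitivities = with_gradient,
                        rtol = obj$rtol, atol = obj$atol)
  if (!sim$success) {
    record_eval(obj, Inf)
    return(list(J = Inf, gradient = NULL, success = FALSE))
  }
  J <- 0
  grad <- if (with_gradient) numeric(length(v)) else NULL
  for (oid in layout$measured) {
    cfg <- obj$configs[[oid]]
    slot <- layout$slots[[oid]]
    rows <- which(obj$data$observableId == oid)
    tk <- obj$data$time[rows]
    ti <- match_times(tk, sim$times)
    y <- sim$observables[oid, ti]
    z <- obj$data$measurement[rows]
    nv <- if ("noiseValue" %in% names(obj$data)) obj$data$noiseValue[rows] else NULL
    if (!is.null(nv) && all(is.na(nv))) nv <- NULL
    sig_known <- resolve_sigma(cfg, nv, length(z))
    reg <- 0; reg_grad <- NULL
    if (slot$class == "quantitative") {
      m <- y; slope <- rep(1, length(y))
    } else if (slot$class == "relative") {
      ab <- v[slot$start + 0:1]
      m <- ab[1] * y + ab[2]; slope <- rep(ab[1], length(y))
    } else {
      xi <- v[slot$start + seq_len(slot$length) - 1L]
      mp <- spline_mapping(obj$fixed_knots[[oid]], pmax(xi, 0))
      Bm <- spline_basis_matrix(mp, y)
      m <- as.numeric(Bm %*% mp$increments)
      slope <- spline_derivative(mp, y)
      lam <- cfg$lambda %||% 0
      rp <- regularization_penalty(mp$increments, lam)
      reg <- rp$value; reg_grad <- rp$gradient
    }
    r <- m - z
    sigma <- if (is.null(sig_known)) max(sqrt(mean(r^2)), SIGMA_FLOOR)
             else sig_known
    J <- J + gauss_nll(r, sigma) + reg
    if (with_gradient) {
      wres <- r / sigma^2
      np_ <- obj$model$np
      io <- match(oid, obj$model$observable_names)
      dy <- matrix(sim$sensitivities[io, ti, , drop = FALSE],
                   nrow = length(ti), ncol = np_)
      chain <- ifelse(obj$bounds$scale == "log10", log(10) * theta_nat, 1)
      grad[seq_len(np_)] <- grad[seq_len(np_)] +
        as.numeric(crossprod(dy, wres * slope)) * chain
      if (slot$class == "relative") {
        grad[slot$start] <- sum(wres * y)
        grad[slot$start + 1L] <- sum(wres)
      } else if (slot$class == "nonlinear_monotone") {
        grad[slot$start + seq_len(slot$length) - 1L] <-
          as.numeric(crossprod(Bm, wres)) + reg_grad
      }
    }
  }
  record_eval(obj, J)
  list(J = J, gradient = grad, success = TRUE)
}

#' Stack the hierarchical inner solution into a joint vector
#'
#' @param obj a \code{hier_objective} with fixed knots.
#' @param theta outer parameters (estimation scale).
#' @param inner inner solutions from \code{evaluate_objective}.
#' @param layout joint layout.
#' @return stacked numeric vector (theta, psi*).
#' @export
stack_joint <- function(obj, theta, inner, layout = NULL) {
  if (is.null(layout)) layout <- joint_layout(obj)
  v <- numeric(layout$n_total)
  v[seq_len(obj$model$np)] <- theta
  for (oid in layout$measured) {
    slot <- layout$slots[[oid]]
    if (slot$length > 0)
      v[slot$start + seq_len(slot$length) - 1L] <-
        as.numeric(inner[[oid]]$psi)
  }
  v
}
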