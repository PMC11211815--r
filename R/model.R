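#' Declarative ODE model specification
#'
#' Defines a dynamical system dx/dt = f(x, theta, t), x(t0) = x0(theta),
#' together with observables y = h(x, theta) and box bounds for the
#' parameters. All expressions are given as strings in R syntax; free
#' symbols must be state names, parameter names, or \code{t}.
#'
#' Parameters are estimated on log10 scale by default (the standard choice
#' for kinetic rate constants, which span orders of magnitude and are
#' positive); bounds are declared on the estimation scale.
#'
#' @param states character vector of state names.
#' @param parameters character vector of parameter names.
#' @param rhs named character vector (one per state) of right-hand-side
#'   expressions, functions of states, parameters and \code{t}.
#' @param init named character vector (one per state) of initial-condition
#'   expressions, functions of parameters only.
#' @param observables named character vector of observable expressions,
#'   functions of states and parameters.
#' @param lower,upper numeric vectors of per-parameter bounds on the
#'   estimation scale (finite, lower < upper).
#' @param scale per-parameter estimation scale, \code{"log10"} or
#'   \code{"lin"}; recycled.
#' @return an object of class \code{ode_model_spec}.
#' @export
ode_model_spec <- function(states, parameters, rhs, init, observables,
                           lower, upper, scale = "log10") {
  states <- as.character(states)
  parameters <- as.character(parameters)
  assert_that(length(rhs) == length(states),
              "need one rhs expression per state (%d vs %d)",
              length(rhs), length(states))
  assert_that(length(init) == length(states),
              "need one initial-condition expression per state")
  assert_that(length(observables) >= 1, "need at least one observable")
  assert_that(!is.null(names(observables)) && all(nzchar(names(observables))),
              "observables must be named")
  scale <- rep_len(match.arg(scale, c("log10", "lin"), several.ok = FALSE),
                   length(parameters))
  lower <- rep_len(as.numeric(lower), length(parameters))
  upper <- rep_len(as.numeric(upper), length(parameters))
  assert_that(all(is.finite(lower)) && all(is.finite(upper)) &&
                all(lower < upper), "bounds must be finite with lower < upper")

  rhs <- stats::setNames(as.character(rhs), states)
  init <- stats::setNames(as.character(init), states)

  spec <- structure(list(
    state_names = states,
    parameter_names = parameters,
    rhs_exprs = rhs,
    init_exprs = init,
    observable_exprs = observables,
    bounds = data.frame(parameter = parameters, lower = lower, upper = upper,
                        scale = scale, stringsAsFactors = FALSE)
  ), class = "ode_model_spec")
  validate_model_spec(spec)
  spec
}

parse_expr1 <- function(txt, what) {
  e <- tryCatch(parse(text = txt)[[1]],
                error = function(err) stop_sq("cannot parse %s '%s': %s",
                                              what, txt, conditionMessage(err)))
  e
}

check_symbols <- function(expr, allowed, what) {
  bad <- setdiff(all.vars(expr), allowed)
  if (length(bad))
    stop_sq("unknown symbol '%s' in %s expression '%s'",
            bad[[1]], what, deparse(expr))
  invisible(TRUE)
}

validate_model_spec <- function(spec) {
  st <- spec$state_names; pa <- spec$parameter_names
  assert_that(!anyDuplicated(c(st, pa, "t")),
              "state/parameter names must be distinct and not 't'")
  for (s in st) {
    check_symbols(parse_expr1(spec$rhs_exprs[[s]], "rhs"), c(st, pa, "t"), "rhs")
    check_symbols(parse_expr1(spec$init_exprs[[s]], "init"), pa, "initial-condition")
  }
  for (o in names(spec$observable_exprs))
    check_symbols(parse_expr1(spec$observable_exprs[[o]], "observable"),
                  c(st, pa, "t"), "observable")
  invisible(spec)
}

#' @export
print.ode_model_spec <- function(x, ...) {
  cat(sprintf("ODE model: %d states, %d parameters, %d observables\n",
              length(x$state_names), length(x$parameter_names),
              length(x$observable_exprs)))
  cat("states:    ", paste(x$state_names, collapse = ", "), "\n")
  cat("parameters:", paste(x$parameter_names, collapse = ", "), "\n")
  cat("observables:", paste(names(x$observable_exprs), collapse = ", "), "\n")
  invisible(x)
}

## Build a single R expression that evaluates to a numeric vector of all
## entries of a symbolically differentiated matrix, column-major, so one
## eval() per call suffices.
matrix_expr <- function(exprs_colmajor) {
  as.call(c(quote(c), exprs_colmajor))
}

#' Compile a model specification into numerical evaluators
#'
#' Parses all expressions once, differentiates them symbolically
#' (\code{stats::D}) and returns closures evaluating the vector field f,
#' its Jacobians df/dx and df/dtheta, the observation map h with dh/dx and
#' dh/dtheta, and the initial condition x0 with dx0/dtheta. These feed the
#' forward sensitivity system and the analytic objective gradient.
#'
#' @param spec an \code{\link{ode_model_spec}}.
#' @return an object of class \code{compiled_model}.
#' @export
compile_model <- function(spec) {
  stopifnot(inherits(spec, "ode_model_spec"))
  validate_model_spec(spec)
  st <- spec$state_names; pa <- spec$parameter_names
  nx <- length(st); np <- length(pa)
  obs <- names(spec$observable_exprs); ny <- length(obs)

  f_ex <- lapply(spec$rhs_exprs, parse_expr1, what = "rhs")
  h_ex <- lapply(spec$observable_exprs, parse_expr1, what = "observable")
  x0_ex <- lapply(spec$init_exprs, parse_expr1, what = "init")

  dmat <- function(exprs, wrt) {
    # column-major list of derivatives: d exprs[i] / d wrt[j]
    out <- vector("list", length(exprs) * length(wrt))
    k <- 1L
    for (j in seq_along(wrt)) for (i in seq_along(exprs)) {
      out[[k]] <- stats::D(exprs[[i]], wrt[[j]]); k <- k + 1L
    }
    matrix_expr(out)
  }

  f_call <- matrix_expr(f_ex)
  h_call <- matrix_expr(h_ex)
  x0_call <- matrix_expr(x0_ex)
  dfdx_call <- dmat(f_ex, st)
  dfdp_call <- dmat(f_ex, pa)
  dhdx_call <- dmat(h_ex, st)
  dhdp_call <- dmat(h_ex, pa)
  dx0dp_call <- dmat(x0_ex, pa)
  ## fused call for the sensitivity right-hand side: one eval() per
  ## integrator step instead of three
  fsys_call <- as.call(c(quote(c), f_ex,
                         as.list(dfdx_call)[-1], as.list(dfdp_call)[-1]))

  ev <- function(call_, env) eval(call_, envir = env, enclos = baseenv())
  mkenv <- function(x, p, t = 0) {
    e <- c(stats::setNames(as.list(x), st), stats::setNames(as.list(p), pa),
           list(t = t))
    e
  }
  mkenv_p <- function(p) stats::setNames(as.list(p), pa)

  structure(list(
    spec = spec, nx = nx, np = np, ny = ny,
    state_names = st, parameter_names = pa, observable_names = obs,
    f = function(x, p, t) as.numeric(ev(f_call, mkenv(x, p, t))),
    dfdx = function(x, p, t) matrix(ev(dfdx_call, mkenv(x, p, t)), nx, nx),
    dfdp = function(x, p, t) matrix(ev(dfdp_call, mkenv(x, p, t)), nx, np),
    h = function(x, p, t = 0) as.numeric(ev(h_call, mkenv(x, p, t))),
    dhdx = function(x, p, t = 0) matrix(ev(dhdx_call, mkenv(x, p, t)), ny, nx),
    dhdp = function(x, p, t = 0) matrix(ev(dhdp_call, mkenv(x, p, t)), ny, np),
    x0 = function(p) as.numeric(ev(x0_call, mkenv_p(p))),
    dx0dp = function(p) matrix(ev(dx0dp_call, mkenv_p(p)), nx, np),
    fsys = function(x, p, t) ev(fsys_call, mkenv(x, p, t))
  ), class = "compiled_model")
}

as_compiled <- function(model) {
  if (inherits(model, "compiled_model")) model else compile_model(model)
}

#' Simulate a model and (optionally) forward sensitivities
#'
#' Integrates the ODE system from t0 = 0 and evaluates the observables at
#' the requested output times. With \code{with_sensitivities = TRUE} the
#' augmented forward sensitivity system
#' \deqn{\dot S = (\partial f/\partial x) S + \partial f/\partial \theta,
#'   \quad S(t_0) = \partial x_0/\partial \theta}
#' is integrated alongside the states and chained through the observation
#' map to give dy/dtheta (natural parameter scale).
#'
#' Integration failures do not raise: they are reported through
#' \code{success} so that optimization loops survive bad parameter draws.
#'
#' @param model an \code{ode_model_spec} or \code{compiled_model}.
#' @param theta named or positional numeric vector of parameters on the
#'   natural (linear) scale.
#' @param times numeric vector of requested output times (sorted,
#'   nonnegative). May be empty.
#' @param with_sensitivities logical; also compute dy/dtheta.
#' @param rtol,atol integrator tolerances.
#' @param method \code{deSolve} integration method (default the
#'   stiff-capable \code{"lsoda"}).
#' @return a list of class \code{sim_result} with elements \code{times},
#'   \code{states} (nx x nt), \code{observables} (ny x nt),
#'   \code{sensitivities} (ny x nt x np array or NULL), \code{success}.
#' @export
simulate_model <- function(model, theta, times, with_sensitivities = FALSE,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  cm <- as_compiled(model)
  nx <- cm$nx; np <- cm$np; ny <- cm$ny
  theta <- as.numeric(theta)
  assert_that(length(theta) == np, "theta has length %d, expected %d",
              length(theta), np)
  times <- as.numeric(times)
  empty <- function(success = TRUE) {
    structure(list(times = numeric(0),
                   states = matrix(0, nx, 0,
                                   dimnames = list(cm$state_names, NULL)),
                   observables = matrix(0, ny, 0,
                                        dimnames = list(cm$observable_names, NULL)),
                   sensitivities = if (with_sensitivities)
                     array(0, c(ny, 0, np)) else NULL,
                   success = success), class = "sim_result")
  }
  if (length(times) == 0) return(empty())
  assert_that(!is.unsorted(times), "times must be sorted")

  x0 <- cm$x0(theta)
  grid <- sort(unique(c(0, times)))

  ix <- seq_len(nx)
  if (with_sensitivities) {
    S0 <- cm$dx0dp(theta)
    y0 <- c(x0, as.vector(S0))
    nfx <- nx + nx * nx
    func <- function(t, y, parms) {
      x <- y[ix]
      S <- matrix(y[-ix], nx, np)
      sys <- cm$fsys(x, theta, t)
      A <- matrix(sys[(nx + 1):nfx], nx, nx)
      Fp <- matrix(sys[(nfx + 1):(nfx + nx * np)], nx, np)
      list(c(sys[ix], A %*% S + Fp))
    }
  } else {
    y0 <- x0
    func <- function(t, y, parms) list(cm$f(y, theta, t))
  }

  out <- tryCatch(
    suppressWarnings(deSolve::ode(y = y0, times = grid, func = func,
                                  parms = NULL, method = method,
                                  rtol = rtol, atol = atol)),
    error = function(e) NULL)
  ok <- !is.null(out) && nrow(out) == length(grid) && all(is.finite(out))
  if (!ok) return(empty(success = FALSE))

  idx <- match(times, grid)
  nt <- length(times)
  states <- matrix(NA_real_, nx, nt, dimnames = list(cm$state_names, NULL))
  obsm <- matrix(NA_real_, ny, nt, dimnames = list(cm$observable_names, NULL))
  sens <- if (with_sensitivities) array(NA_real_, c(ny, nt, np)) else NULL
  for (k in seq_len(nt)) {
    row <- out[idx[k], -1]
    x <- row[seq_len(nx)]
    states[, k] <- x
    obsm[, k] <- cm$h(x, theta, times[k])
    if (with_sensitivities) {
      S <- matrix(row[-seq_len(nx)], nx, np)
      sens[, k, ] <- cm$dhdx(x, theta, times[k]) %*% S +
        cm$dhdp(x, theta, times[k])
    }
  }
  structure(list(times = times, states = states, observables = obsm,
                 sensitivities = sens, success = TRUE),
            class = "sim_result")
}
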