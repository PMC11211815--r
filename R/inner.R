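SIGMA_FLOOR <- 1e-10

#' Per-observable measurement-mapping configuration
#'
#' Declares how an observable's measurements relate to the model
#' observable: directly (\code{quantitative}), through an unknown affine
#' scaling/offset (\code{relative}), or through an unknown monotone
#' nonlinear mapping reconstructed by the spline (\code{nonlinear_monotone}).
#' The noise standard deviation on the measurement scale is either known
#' or estimated as a single per-observable parameter.
#'
#' @param observable_id observable name (must exist in the model).
#' @param mapping_class one of \code{"quantitative"}, \code{"relative"},
#'   \code{"nonlinear_monotone"}.
#' @param noise_mode \code{"estimate_single"} or \code{"known"}.
#' @param known_sigma positive scalar, required when \code{noise_mode =
#'   "known"} (per-time-point values can instead be supplied in the
#'   measurement table's \code{noiseValue} column).
#' @param n_knots,margin spline grid settings (nonlinear observables).
#' @param lambda linearity-regularization strength; 0 disables.
#' @return an \code{observable_config} object.
#' @export
observable_config <- function(observable_id,
                              mapping_class = c("quantitative", "relative",
                                                "nonlinear_monotone"),
                              noise_mode = c("estimate_single", "known"),
                              known_sigma = NULL,
                              n_knots = 8, margin = 0.3, lambda = 1e-2) {
  mapping_class <- match.arg(mapping_class)
  noise_mode <- match.arg(noise_mode)
  if (noise_mode == "known")
    assert_that(is.null(known_sigma) || (is.numeric(known_sigma) &&
                  known_sigma > 0),
                "known_sigma must be a positive scalar")
  structure(list(observable_id = observable_id,
                 mapping_class = mapping_class,
                 noise_mode = noise_mode,
                 known_sigma = known_sigma,
                 n_knots = n_knots, margin = margin, lambda = lambda),
            class = "observable_config")
}

gauss_nll <- function(residuals, sigma) {
  # sigma scalar or per-point vector, already floored
  sum(0.5 * log(2 * pi * sigma^2) + residuals^2 / (2 * sigma^2))
}

inner_solution <- function(observable_id, mapping_class, psi, sigma, J,
                           residuals, mapped, slope, mapping = NULL,
                           flags = character(0)) {
  structure(list(observable_id = observable_id,
                 mapping_class = mapping_class,
                 psi = psi, sigma = sigma, J = J,
                 residuals = residuals, mapped = mapped, slope = slope,
                 mapping = mapping, flags = flags),
            class = "inner_solution")
}

resolve_sigma <- function(cfg, noise_values, nt) {
  ## returns per-point known sigmas, or NULL when sigma is to be estimated
  if (!is.null(noise_values) && any(is.finite(noise_values))) {
    assert_that(all(is.finite(noise_values)) && all(noise_values > 0),
                "noiseValue entries must all be positive when present")
    return(rep_len(noise_values, nt))
  }
  if (cfg$noise_mode == "known") {
    assert_that(!is.null(cfg$known_sigma),
                "noise_mode='known' for '%s' but no sigma supplied",
                cfg$observable_id)
    return(rep_len(cfg$known_sigma, nt))
  }
  NULL
}

#' Closed-form inner solution for a relative (affine) observable
#'
#' Profiles the scaling a, offset b (ordinary or noise-weighted least
#' squares) and, if requested, the single Gaussian noise SD (maximum
#' likelihood: root-mean-square residual) for measurements z related to
#' simulated observable values y by z = a*y + b + noise.
#'
#' @param y simulated observable values.
#' @param z measurements, same length.
#' @param cfg an \code{observable_config} with \code{mapping_class = "relative"}.
#' @param noise_values optional per-point known noise SDs.
#' @return an \code{inner_solution} with \code{psi = c(a, b)}.
#' @export
solve_relative <- function(y, z, cfg, noise_values = NULL) {
  nt <- length(y)
  assert_that(length(z) == nt, "y and z lengths differ")
  sig_known <- resolve_sigma(cfg, noise_values, nt)
  w <- if (is.null(sig_known)) rep(1, nt) else 1 / sig_known^2
  yb <- sum(w * y) / sum(w); zb <- sum(w * z) / sum(w)
  syy <- sum(w * (y - yb)^2)
  flags <- character(0)
  if (syy <= .Machine$double.eps * max(1, sum(w * y^2))) {
    a <- 0; b <- zb
    flags <- "nonidentifiable_scaling"
  } else {
    a <- sum(w * (y - yb) * (z - zb)) / syy
    b <- zb - a * yb
  }
  m <- a * y + b
  r <- m - z
  sigma <- if (is.null(sig_known)) max(sqrt(mean(r^2)), SIGMA_FLOOR)
           else sig_known
  inner_solution(cfg$observable_id, "relative", psi = c(a = a, b = b),
                 sigma = sigma, J = gauss_nll(r, sigma),
                 residuals = r, mapped = m, slope = rep(a, nt),
                 flags = flags)
}

#' Inner solution for a quantitative observable
#'
#' Identity mapping; only the noise SD is profiled when requested.
#'
#' @inheritParams solve_relative
#' @export
solve_quantitative <- function(y, z, cfg, noise_values = NULL) {
  nt <- length(y)
  assert_that(length(z) == nt, "y and z lengths differ")
  sig_known <- resolve_sigma(cfg, noise_values, nt)
  r <- y - z
  sigma <- if (is.null(sig_known)) max(sqrt(mean(r^2)), SIGMA_FLOOR)
           else sig_known
  inner_solution(cfg$observable_id, "quantitative", psi = NULL,
                 sigma = sigma, J = gauss_nll(r, sigma),
                 residuals = r, mapped = y, slope = rep(1, nt))
}

## One nonnegative least-squares solve of the Tikhonov-augmented system:
## minimize 0.5*sum(((B xi)_k - z_k)/sig_k)^2 + 0.5*lam2*||M xi||^2, xi>=0,
## where M = I - (1/n) 11' centers the increments.
nnls_spline <- function(B, z, sig, lam2) {
  n <- ncol(B)
  A <- B / sig
  b <- z / sig
  if (lam2 > 0) {
    M <- diag(n) - matrix(1 / n, n, n)
    A <- rbind(A, sqrt(lam2) * M)
    b <- c(b, rep(0, n))
  }
  sol <- pracma::lsqnonneg(A, b)
  pmax(sol$x, 0)
}

#' Convex inner solution for a nonlinear-monotone (spline) observable
#'
#' Minimizes the penalized Gaussian negative log-likelihood
#' \deqn{\frac{1}{2\sigma^2}\|z - B\xi\|^2 +
#'   \frac{\lambda}{2}\|\xi - \bar\xi 1\|^2 \quad \text{s.t. } \xi \ge 0}
#' over the spline height increments, where B is the spline basis matrix
#' at the simulated values y. Solved as nonnegative least squares on the
#' Tikhonov-augmented system, a robust reformulation of the convex QP.
#' With an estimated single noise SD and lambda > 0 the sigma-lambda
#' coupling is resolved by a short fixed-point iteration (solve xi at the
#' current sigma, update sigma from the residuals, re-solve), preserving
#' per-step convexity.
#'
#' @param y simulated observable values (knot grid spans their range
#'   unless \code{knots} is supplied).
#' @param z measurements, same length.
#' @param cfg an \code{observable_config} with
#'   \code{mapping_class = "nonlinear_monotone"}.
#' @param noise_values optional per-point known noise SDs.
#' @param knots optional fixed knot grid (default: \code{make_knot_grid}
#'   on \code{y} with the config's settings).
#' @return an \code{inner_solution} carrying the fitted
#'   \code{spline_mapping} and increments \code{psi = xi}.
#' @export
solve_spline_inner <- function(y, z, cfg, noise_values = NULL, knots = NULL) {
  nt <- length(y)
  assert_that(length(z) == nt, "y and z lengths differ")
  if (nt < cfg$n_knots + 1)
    warning(sprintf("observable '%s': %d data points for %d spline knots; fit may be underdetermined",
                    cfg$observable_id, nt, cfg$n_knots))
  if (is.null(knots)) knots <- make_knot_grid(y, cfg$n_knots, cfg$margin)
  n <- length(knots)
  B <- spline_basis_matrix(knots, y)
  lam <- cfg$lambda %||% 0
  sig_known <- resolve_sigma(cfg, noise_values, nt)

  if (!is.null(sig_known)) {
    xi <- nnls_spline(B, z, sig_known, lam)
    sigma <- sig_known
  } else {
    ## estimated single sigma: the minimizing xi is independent of sigma
    ## when lam == 0; otherwise fixed-point on (xi, sigma), iterated to
    ## joint stationarity so the envelope gradient identity holds tightly
    sigma2 <- 1
    xi_prev <- NULL
    for (it in seq_len(if (lam > 0) 100L else 1L)) {
      xi <- nnls_spline(B, z, rep(1, nt), lam * sigma2)
      r <- as.numeric(B %*% xi) - z
      s2_new <- max(mean(r^2), SIGMA_FLOOR^2)
      conv <- !is.null(xi_prev) &&
        max(abs(xi - xi_prev)) <= 1e-12 * max(1, max(abs(xi))) &&
        abs(s2_new - sigma2) <= 1e-12 * s2_new
      sigma2 <- s2_new
      if (conv) break
      xi_prev <- xi
    }
    sigma <- sqrt(sigma2)
  }

  m <- as.numeric(B %*% xi)
  r <- m - z
  mapping <- spline_mapping(knots, xi)
  J <- gauss_nll(r, sigma) + regularization_penalty(xi, lam)$value
  inner_solution(cfg$observable_id, "nonlinear_monotone",
                 psi = xi, sigma = sigma, J = J,
                 residuals = r, mapped = m,
                 slope = spline_derivative(mapping, y),
                 mapping = mapping)
}

#' Solve all per-observable inner problems
#'
#' The hierarchical objective separates additively over observables, so
#' each observable's mapping/noise parameters are profiled independently;
#' results do not depend on observable order.
#'
#' @param sim a successful \code{sim_result}.
#' @param data a measurement data frame (columns \code{observableId},
#'   \code{time}, \code{measurement}, optional \code{noiseValue}).
#' @param configs list of \code{observable_config}s covering every
#'   measured observable.
#' @param fixed_knots optional named list of knot grids overriding the
#'   per-evaluation adaptive grid for spline observables.
#' @return list of \code{inner_solution}s, named by observable.
#' @export
solve_inner_all <- function(sim, data, configs, fixed_knots = NULL) {
  assert_that(isTRUE(sim$success), "simulation failed; no inner solve")
  cfg_ids <- vapply(configs, function(cf) cf$observable_id, character(1))
  names(configs) <- cfg_ids
  out <- list()
  for (oid in unique(data$observableId)) {
    if (!oid %in% cfg_ids)
      stop_sq("no observable_config for measured observable '%s'", oid)
    if (!oid %in% rownames(sim$observables))
      stop_sq("measured observable '%s' not in model", oid)
    cfg <- configs[[oid]]
    rows <- which(data$observableId == oid)
    tk <- data$time[rows]
    ti <- match_times(tk, sim$times)
    y <- sim$observables[oid, ti]
    z <- data$measurement[rows]
    nv <- if ("noiseValue" %in% names(data)) data$noiseValue[rows] else NULL
    if (!is.null(nv) && all(is.na(nv))) nv <- NULL
    sol <- switch(cfg$mapping_class,
      quantitative = solve_quantitative(y, z, cfg, nv),
      relative = solve_relative(y, z, cfg, nv),
      nonlinear_monotone = solve_spline_inner(
        y, z, cfg, nv, knots = fixed_knots[[oid]]))
    sol$time_index <- ti
    sol$y <- y
    out[[oid]] <- sol
  }
  out
}

match_times <- function(tk, sim_times, tol = 1e-9) {
  idx <- vapply(tk, function(t) {
    j <- which(abs(sim_times - t) <= tol * max(1, abs(t)))
    if (!length(j))
      stop_sq("measurement time %g not present in the simulation grid", t)
    j[[1]]
  }, integer(1))
  idx
}
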