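#' FRET probe-activation benchmark model
#'
#' Two-state probe model: a forward enzyme activates inactive probes P to
#' the active state Pstar and a reverse enzyme deactivates them, with the
#' enzyme levels lumped into effective first-order rates k1 (activation)
#' and k2 (deactivation). Total probe is conserved, x0 = (PTOT, 0). The
#' quantity of interest is the active fraction Pstar/PTOT
#' (\code{active_fraction}); the second observable \code{fret_ratio} is
#' the parametric ratiometric-imaging readout
#' alpha * Pstar / (PTOT - Pstar) + beta, used when the measurement
#' mapping is treated as known-up-to-parameters rather than reconstructed
#' by a spline. Either way the model carries 4 estimable parameters
#' (k1, k2, alpha, beta), all on log10 scale with bounds [-2, 2].
#'
#' @param PTOT total probe concentration (fixed, not estimated).
#' @return an \code{ode_model_spec}.
#' @export
build_fret_model <- function(PTOT = 10) {
  assert_that(PTOT > 0, "PTOT must be positive")
  pt <- format(PTOT, digits = 17)
  ode_model_spec(
    states = c("P", "Pstar"),
    parameters = c("k1", "k2", "alpha", "beta"),
    rhs = c(P = "-k1*P + k2*Pstar", Pstar = "k1*P - k2*Pstar"),
    init = c(P = pt, Pstar = "0"),
    observables = c(
      active_fraction = sprintf("Pstar/%s", pt),
      fret_ratio = sprintf("alpha*Pstar/(%s - Pstar) + beta", pt)),
    lower = c(-2, -2, -2, -2), upper = c(2, 2, 2, 2))
}

#' Ratiometric FRET measurement mapping
#'
#' The readout of ratiometric imaging as a function of the active probe
#' concentration: g(Pstar) = alpha * Pstar / (PTOT - Pstar) + beta, a
#' strictly increasing map with a pole at full activation.
#'
#' @param P_star active probe concentration, 0 <= P_star < PTOT.
#' @param PTOT total probe concentration.
#' @param alpha gain (dimensionless).
#' @param beta baseline offset.
#' @export
fret_mapping <- function(P_star, PTOT, alpha, beta) {
  assert_that(all(is.finite(P_star)), "P_star must be finite")
  if (any(P_star >= PTOT))
    stop_sq("P_star >= PTOT: the ratiometric mapping has a pole at full activation")
  alpha * P_star / (PTOT - P_star) + beta
}

#' Default truth and protocol for the FRET benchmark
#'
#' True parameters (k1 = 2, k2 = 1 per time unit; mapping gain alpha = 1,
#' offset beta = 0.2), 12 log-spaced measurement times covering the
#' activation transient (relaxation rate k1 + k2 = 3), and measurement
#' noise SD 0.05 on the mapped scale (a few percent of the readout
#' dynamic range).
#'
#' @return list with \code{theta_true} (natural scale, named),
#'   \code{theta_true_log10}, \code{times}, \code{sigma}, \code{PTOT}.
#' @export
t1_protocol <- function() {
  theta <- c(k1 = 2, k2 = 1, alpha = 1, beta = 0.2)
  list(theta_true = theta,
       theta_true_log10 = log10(theta),
       times = 10^seq(log10(0.05), log10(5), length.out = 12),
       sigma = 0.05,
       PTOT = 10)
}

monotone_entry <- function(name, fn, params, range) {
  xs <- seq(range[1], range[2], length.out = 400)
  v <- fn(xs)
  assert_that(all(diff(v) >= -1e-12),
              "mapping '%s' is not monotone on its declared range", name)
  list(name = name, fn = fn, params = params, range = range)
}

#' Library of monotone synthetic measurement mappings
#'
#' A set of monotone shapes used to corrupt synthetic observables:
#' identity, affine, saturating hyperbola v*x/(K+x), exponential
#' saturation v*(1-exp(-x/tau)), power laws x^p for p in {0.5, 2}, and a
#' soft-threshold sigmoid. Every entry is verified nondecreasing on its
#' declared range at construction.
#'
#' @param range common input range the entries are declared on.
#' @return named list of entries (name, fn, params, range).
#' @export
mapping_library <- function(range = c(0, 1)) {
  list(
    identity = monotone_entry("identity", function(x) x, list(), range),
    affine = monotone_entry("affine", function(x) 2 * x + 0.5,
                            list(a = 2, b = 0.5), range),
    hyperbola = monotone_entry("hyperbola",
                               function(x) 1 * x / (0.3 + x),
                               list(v = 1, K = 0.3), range),
    exp_saturation = monotone_entry("exp_saturation",
                                    function(x) 1 * (1 - exp(-x / 0.25)),
                                    list(v = 1, tau = 0.25), range),
    power_half = monotone_entry("power_half", function(x) x^0.5,
                                list(p = 0.5), range),
    power_two = monotone_entry("power_two", function(x) x^2,
                               list(p = 2), range),
    sigmoid = monotone_entry("sigmoid",
                             function(x) 1 / (1 + exp(-(x - 0.5) / 0.08)),
                             list(mid = 0.5, slope = 0.08), range)
  )
}

#' Three-observable cascade benchmark model
#'
#' Linear chain of first-order conversions A -> B -> C with degradation
#' of C. The observables are combined readouts (A + C, B, B + C) rather
#' than the pure species — the common situation where probes do not
#' discriminate between species and only sums of concentrations are
#' measurable. The mixtures are what make the fixture identifiable when
#' every observable carries an unknown monotone mapping: pure-species
#' observables leave an exact k1/k2 exchange symmetry (B swaps to a
#' proportional curve, which a free mapping absorbs; C is
#' swap-invariant; the monotone A is always mapping-compensable),
#' whereas the mixtures change shape — not just scale — under parameter
#' exchanges and their non-monotone time profiles cannot be absorbed by
#' any monotone measurement mapping.
#'
#' @return an \code{ode_model_spec} with states A, B, C and parameters
#'   k1, k2, k3 (log10 bounds [-2, 2]).
#' @export
build_cascade_model <- function() {
  ode_model_spec(
    states = c("A", "B", "C"),
    parameters = c("k1", "k2", "k3"),
    rhs = c(A = "-k1*A", B = "k1*A - k2*B", C = "k2*B - k3*C"),
    init = c(A = "1", B = "0", C = "0"),
    observables = c(obs_AC = "A + C", obs_B = "B", obs_BC = "B + C"),
    lower = c(-2, -2, -2), upper = c(2, 2, 2))
}

#' Default truth and protocol for the cascade benchmark
#'
#' @return list with \code{theta_true}, \code{theta_true_log10},
#'   \code{times} (16 log-spaced points over the cascade transient),
#'   \code{sigma} (per observable), \code{mappings} (names from
#'   \code{\link{mapping_library}} per observable).
#' @export
cascade_protocol <- function() {
  theta <- c(k1 = 1.5, k2 = 0.8, k3 = 0.4)
  list(theta_true = theta,
       theta_true_log10 = log10(theta),
       times = 10^seq(log10(0.1), log10(12), length.out = 16),
       sigma = c(obs_AC = 0.05, obs_B = 0.05, obs_BC = 0.05),
       mappings = c(obs_AC = "hyperbola", obs_B = "exp_saturation",
                    obs_BC = "power_half"))
}

#' Generate a synthetic semi-quantitative dataset
#'
#' Simulates the model at the true parameters, pushes each observable
#' through its monotone measurement mapping, and corrupts the mapped
#' values with i.i.d. Gaussian noise on the measurement scale.
#'
#' @param model an \code{ode_model_spec} or \code{compiled_model}.
#' @param theta_true true parameters (natural scale).
#' @param times measurement times.
#' @param mappings named list of monotone functions (or
#'   \code{mapping_library} entries), one per measured observable;
#'   observables not listed are not measured.
#' @param sigma named numeric vector of noise SDs per observable (> 0;
#'   may be 0 for noiseless data).
#' @param seed RNG seed.
#' @return list of class \code{synthetic_dataset} with \code{data}
#'   (measurement data frame), \code{theta_true}, \code{mappings},
#'   \code{sigma}, \code{seed}, \code{y_true} and \code{z_true}
#'   (noiseless observables and mapped values).
#' @export
generate_dataset <- function(model, theta_true, times, mappings, sigma,
                             seed = 1) {
  cm <- as_compiled(model)
  ids <- names(mappings)
  assert_that(!is.null(ids) && all(ids %in% cm$observable_names),
              "mappings must be named by model observables")
  assert_that(all(ids %in% names(sigma)), "sigma must cover every mapped observable")
  assert_that(all(sigma[ids] >= 0), "sigma must be nonnegative")
  sim <- simulate_model(cm, theta_true, times)
  assert_that(sim$success, "simulation at theta_true failed")
  set.seed(seed)
  rows <- list()
  y_true <- list(); z_true <- list()
  for (oid in ids) {
    fn <- mappings[[oid]]
    if (is.list(fn)) fn <- fn$fn
    y <- sim$observables[oid, ]
    z <- fn(y)
    assert_that(all(is.finite(z)),
                "mapping for '%s' produced non-finite values", oid)
    zt <- z + stats::rnorm(length(z), 0, sigma[[oid]])
    rows[[oid]] <- data.frame(observableId = oid, time = times,
                              measurement = zt, stringsAsFactors = FALSE)
    y_true[[oid]] <- y; z_true[[oid]] <- z
  }
  structure(list(data = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 theta_true = theta_true, mappings = mappings,
                 sigma = sigma, seed = seed,
                 times = times, y_true = y_true, z_true = z_true),
            class = "synthetic_dataset")
}

#' T1 FRET dataset generated by the default protocol
#'
#' Convenience wrapper: 12 noisy measurements of the active fraction
#' pushed through the true ratiometric mapping.
#'
#' @param seed RNG seed.
#' @param sigma noise SD on the mapped scale (default from
#'   \code{\link{t1_protocol}}).
#' @return a \code{synthetic_dataset} (plus \code{$model} and
#'   \code{$protocol}).
#' @export
t1_dataset <- function(seed = 1, sigma = NULL) {
  pr <- t1_protocol()
  if (is.null(sigma)) sigma <- pr$sigma
  model <- build_fret_model(pr$PTOT)
  ## the mapping acts on the active-fraction observable y = Pstar/PTOT:
  ## g(y) = alpha * y / (1 - y) + beta
  g <- function(y) pr$theta_true[["alpha"]] * y / (1 - y) +
    pr$theta_true[["beta"]]
  ds <- generate_dataset(model, pr$theta_true, pr$times,
                         mappings = list(active_fraction = g),
                         sigma = c(active_fraction = sigma), seed = seed)
  ds$model <- model
  ds$protocol <- pr
  ds
}

#' Cascade dataset generated by the default protocol
#'
#' @param seed RNG seed.
#' @return a \code{synthetic_dataset} (plus \code{$model},
#'   \code{$protocol} and the truth mapping functions).
#' @export
cascade_dataset <- function(seed = 1) {
  pr <- cascade_protocol()
  model <- build_cascade_model()
  lib <- mapping_library()
  maps <- lapply(pr$mappings, function(nm) lib[[nm]])
  names(maps) <- names(pr$mappings)
  ds <- generate_dataset(model, pr$theta_true, pr$times, maps, pr$sigma,
                         seed = seed)
  ds$model <- model
  ds$protocol <- pr
  ds
}
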