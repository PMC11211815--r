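#' Adaptive Metropolis sampler on a box
#'
#' Random-walk Metropolis with a Gaussian proposal whose covariance is
#' adapted from the chain history and whose global scale is tuned toward
#' the canonical multivariate target acceptance rate of about 0.234.
#' Adaptation runs only during the warm-up portion of the chain (default
#' first 20%) and is frozen afterwards, preserving the correctness of the
#' post-warm-up chain as a Markov chain. Proposals outside the box have
#' zero prior mass and are rejected.
#'
#' @param log_target function(theta) returning the log target density
#'   (up to a constant); may return -Inf.
#' @param theta0 starting point (finite log target).
#' @param lower,upper box bounds.
#' @param n_iter total iterations.
#' @param seed RNG seed.
#' @param warmup_frac fraction of iterations used for adaptation.
#' @param target_accept acceptance rate the scale adaptation aims for.
#' @param cov_eps jitter added to the adapted covariance for positive
#'   definiteness.
#' @return list with \code{chain} (n_iter x d), \code{log_target} trace,
#'   \code{accept_rate} (post-warm-up), \code{n_warmup}.
#' @export
adaptive_metropolis <- function(log_target, theta0, lower, upper,
                                n_iter = 10000, seed = 1,
                                warmup_frac = 0.2, target_accept = 0.234,
                                cov_eps = 1e-8) {
  d <- length(theta0)
  assert_that(length(lower) == d && length(upper) == d, "bounds length mismatch")
  lp0 <- log_target(theta0)
  assert_that(is.finite(lp0), "log target must be finite at theta0")
  set.seed(seed)
  n_warm <- max(10L, floor(warmup_frac * n_iter))
  chain <- matrix(NA_real_, n_iter, d)
  lps <- numeric(n_iter)
  theta <- theta0; lp <- lp0
  ## running moments for covariance adaptation
  rng <- upper - lower
  rng[!is.finite(rng)] <- 1
  mu <- theta; Sig <- diag((pmax(rng, 1e-8) / 20)^2, d)
  log_s <- 0
  base_scale <- 2.38^2 / d
  L <- chol(base_scale * Sig + cov_eps * diag(d))
  acc_post <- 0L; n_post <- 0L
  for (i in seq_len(n_iter)) {
    prop <- theta + exp(log_s) * as.numeric(crossprod(L, stats::rnorm(d)))
    lp_prop <- if (any(prop < lower | prop > upper)) -Inf else log_target(prop)
    a <- min(1, exp(lp_prop - lp))
    if (is.finite(lp_prop) && stats::runif(1) < a) {
      theta <- prop; lp <- lp_prop
    }
    chain[i, ] <- theta; lps[i] <- lp
    if (i <= n_warm) {
      ## Robbins-Monro scale adaptation + running covariance update
      log_s <- log_s + (a - target_accept) / i^0.6
      w <- 1 / (i + 1)
      dlt <- theta - mu
      mu <- mu + w * dlt
      Sig <- Sig + w * (tcrossprod(dlt) - Sig)
      if (i %% 25 == 0 || i == n_warm)
        L <- chol(base_scale * Sig + cov_eps * diag(d))
    } else {
      n_post <- n_post + 1L
      if (is.finite(lp_prop) && a > 0 &&
          all(chain[i, ] == prop)) acc_post <- acc_post + 1L
    }
  }
  if (n_post > 0 && acc_post == 0L)
    stop_sq("no accepted moves after warm-up; check the target or bounds")
  list(chain = chain, log_target = lps,
       accept_rate = if (n_post > 0) acc_post / n_post else NA_real_,
       n_warmup = n_warm)
}

#' Posterior sampling of the mechanistic parameters with mapping bands
#'
#' Samples the hierarchical likelihood surface over the mechanistic
#' parameters with a uniform prior over the (log10) bounds — mapping and
#' noise parameters are profiled out inside the likelihood, so each
#' posterior sample induces an optimal measurement mapping. The retained
#' (thinned) samples yield pointwise credibility bands for the
#' reconstructed mapping of every spline observable.
#'
#' @param obj a \code{hier_objective}.
#' @param theta_init starting point on the estimation scale (typically
#'   the multi-start optimum; must have finite objective).
#' @param n_iter total MCMC iterations.
#' @param thin thinning factor (retain every thin-th sample).
#' @param seed RNG seed.
#' @param level credibility level of the bands (default 0.95).
#' @param band_grid_n number of mapping-evaluation grid points.
#' @return a \code{sample_result}: retained \code{chain}, full
#'   \code{log_target} trace, \code{accept_rate}, \code{thin},
#'   \code{mappings} (per retained sample), \code{bands} (per spline
#'   observable: x, lower, upper, median, level).
#' @export
sample_posterior <- function(obj, theta_init, n_iter = 10000, thin = 50,
                             seed = 1, level = 0.95, band_grid_n = 50) {
  stopifnot(inherits(obj, "hier_objective"))
  assert_that(thin >= 1 && thin <= n_iter, "need 1 <= thin <= n_iter")
  lo <- obj$bounds$lower; hi <- obj$bounds$upper
  log_target <- function(theta) {
    ev <- evaluate_objective(obj, theta, with_gradient = FALSE)
    if (!ev$success) -Inf else -ev$J
  }
  run <- adaptive_metropolis(log_target, theta_init, lo, hi,
                             n_iter = n_iter, seed = seed)
  keep <- seq(thin, n_iter, by = thin)
  chain <- run$chain[keep, , drop = FALSE]
  colnames(chain) <- obj$model$parameter_names

  ## per retained sample: profile the mappings and evaluate them on a
  ## fixed grid anchored at the initial point's spline coverage
  spline_ids <- names(Filter(function(cf)
    cf$mapping_class == "nonlinear_monotone", obj$configs))
  spline_ids <- intersect(spline_ids, unique(obj$data$observableId))
  ev0 <- evaluate_objective(obj, theta_init, with_gradient = FALSE)
  grids <- lapply(spline_ids, function(oid) {
    kmax <- max(ev0$inner[[oid]]$mapping$knots)
    seq(0, kmax, length.out = band_grid_n)
  })
  names(grids) <- spline_ids

  mappings <- vector("list", nrow(chain))
  vals <- lapply(spline_ids, function(oid)
    matrix(NA_real_, nrow(chain), band_grid_n))
  names(vals) <- spline_ids
  for (s in seq_len(nrow(chain))) {
    ev <- evaluate_objective(obj, chain[s, ], with_gradient = FALSE)
    if (!ev$success) next
    mappings[[s]] <- lapply(ev$inner[spline_ids], function(sol) sol$mapping)
    for (oid in spline_ids)
      vals[[oid]][s, ] <- eval_spline(ev$inner[[oid]]$mapping, grids[[oid]])
  }
  qs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  bands <- lapply(spline_ids, function(oid) {
    v <- vals[[oid]][stats::complete.cases(vals[[oid]]), , drop = FALSE]
    q <- apply(v, 2, stats::quantile, probs = qs, names = FALSE)
    data.frame(x = grids[[oid]], lower = q[1, ], median = q[2, ],
               upper = q[3, ], level = level)
  })
  names(bands) <- spline_ids

  structure(list(chain = chain, log_target = run$log_target,
                 accept_rate = run$accept_rate, thin = thin,
                 mappings = mappings, bands = bands, seed = seed,
                 n_iter = n_iter),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("MCMC sample: %d retained of %d iterations (thin %d), acceptance %.3f\n",
              nrow(x$chain), x$n_iter, x$thin, x$accept_rate))
  invisible(x)
}
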