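## Shared fixtures, built once per test run.

t1_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- t1_dataset(seed = 1)
      cfg <- list(observable_config("active_fraction", "nonlinear_monotone"))
      obj <- hier_objective(ds$model, ds$data, cfg)
      ev0 <- evaluate_objective(obj, ds$protocol$theta_true_log10,
                                with_gradient = FALSE)
      fk <- list(active_fraction = ev0$inner$active_fraction$mapping$knots)
      cache <<- list(ds = ds, cfg = cfg, obj = obj, fixed_knots = fk,
                     pr = ds$protocol)
    }
    cache
  }
})

## two-state reversible conversion, used for Jacobian/FD checks
twostate_spec <- function() {
  ode_model_spec(
    states = c("A", "B"),
    parameters = c("kf", "kb"),
    rhs = c(A = "-kf*A + kb*B", B = "kf*A - kb*B"),
    init = c(A = "1", B = "0"),
    observables = c(total = "A + 2*B"),
    lower = c(-2, -2), upper = c(2, 2))
}

## random monotone spline instance
random_mapping <- function(n = 6, dc = 0.5) {
  spline_mapping(seq_len(n) * dc, stats::runif(n, 0, 2))
}
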