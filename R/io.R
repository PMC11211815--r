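#' Read a measurement table
#'
#' Tab-separated table with columns \code{observableId}, \code{time},
#' \code{measurement} and optionally \code{noiseValue} (known per-point
#' noise SD). Rows are returned in stable (observable, time) order.
#'
#' @param path TSV file path.
#' @param observable_ids optional character vector of valid observable
#'   ids; unknown ids raise an error naming the offending row.
#' @return data frame.
#' @export
read_measurements <- function(path, observable_ids = NULL) {
  assert_that(file.exists(path), "measurement file '%s' not found", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("observableId", "time", "measurement")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_sq("measurement table '%s' is missing column '%s'", path, miss[[1]])
  if (nrow(df) == 0) {
    warning(sprintf("measurement table '%s' is empty", path))
    return(df)
  }
  for (col in c("time", "measurement")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_sq("non-numeric or non-finite value in column '%s', row %d of '%s'",
              col, bad[[1]], path)
    df[[col]] <- v
  }
  if ("noiseValue" %in% names(df))
    df$noiseValue <- suppressWarnings(as.numeric(df$noiseValue))
  if (!is.null(observable_ids)) {
    bad <- which(!df$observableId %in% observable_ids)
    if (length(bad))
      stop_sq("unknown observable '%s' in row %d of '%s'",
              df$observableId[bad[[1]]], bad[[1]], path)
  }
  df[order(df$observableId, df$time), , drop = FALSE]
}

#' Write a measurement table
#' @param data measurement data frame.
#' @param path output TSV path.
#' @export
write_measurements <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model definition from YAML
#'
#' Expected sections: \code{states}, \code{parameters} (each with
#' \code{name}, \code{lower}, \code{upper}, optional \code{scale}),
#' \code{odes}, \code{initial}, \code{observables} (maps name ->
#' expression string).
#'
#' @param path YAML file path.
#' @return an \code{ode_model_spec}.
#' @export
read_model_yaml <- function(path) {
  assert_that(file.exists(path), "model file '%s' not found", path)
  y <- yaml::read_yaml(path)
  for (sec in c("states", "parameters", "odes", "initial", "observables"))
    assert_that(!is.null(y[[sec]]), "model file '%s' lacks section '%s'",
                path, sec)
  pnames <- vapply(y$parameters, function(p) as.character(p$name), character(1))
  lower <- vapply(y$parameters, function(p) as.numeric(p$lower), numeric(1))
  upper <- vapply(y$parameters, function(p) as.numeric(p$upper), numeric(1))
  scale <- vapply(y$parameters, function(p)
    as.character(p$scale %||% "log10"), character(1))
  states <- as.character(unlist(y$states))
  spec <- ode_model_spec(
    states = states,
    parameters = pnames,
    rhs = vapply(states, function(s) as.character(y$odes[[s]]), character(1)),
    init = vapply(states, function(s) as.character(y$initial[[s]]), character(1)),
    observables = stats::setNames(
      vapply(y$observables, as.character, character(1)), names(y$observables)),
    lower = lower, upper = upper, scale = scale[1])
  spec$bounds$scale <- scale
  spec
}

#' Write a model definition to YAML
#' @param spec an \code{ode_model_spec}.
#' @param path output YAML path.
#' @export
write_model_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "ode_model_spec"))
  y <- list(
    states = as.list(spec$state_names),
    parameters = lapply(seq_len(nrow(spec$bounds)), function(i)
      list(name = spec$bounds$parameter[i], lower = spec$bounds$lower[i],
           upper = spec$bounds$upper[i], scale = spec$bounds$scale[i])),
    odes = as.list(spec$rhs_exprs),
    initial = as.list(spec$init_exprs),
    observables = as.list(spec$observable_exprs))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read observable configurations from TSV
#'
#' Columns: \code{observableId}, \code{mappingClass}, optional
#' \code{noiseMode}, \code{knownSigma}, \code{nKnots}, \code{lambda}.
#'
#' @param path TSV file path.
#' @return list of \code{observable_config}s.
#' @export
read_observable_configs <- function(path) {
  assert_that(file.exists(path), "observable file '%s' not found", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("observableId", "mappingClass") %in% names(df)),
              "observable table needs columns observableId, mappingClass")
  lapply(seq_len(nrow(df)), function(i) {
    ks <- if ("knownSigma" %in% names(df) && is.finite(df$knownSigma[i]))
      df$knownSigma[i] else NULL
    observable_config(
      observable_id = df$observableId[i],
      mapping_class = df$mappingClass[i],
      noise_mode = if ("noiseMode" %in% names(df) && !is.na(df$noiseMode[i]))
        df$noiseMode[i] else if (!is.null(ks)) "known" else "estimate_single",
      known_sigma = ks,
      n_knots = if ("nKnots" %in% names(df) && is.finite(df$nKnots[i]))
        df$nKnots[i] else 8,
      lambda = if ("lambda" %in% names(df) && is.finite(df$lambda[i]))
        df$lambda[i] else 1e-2)
  })
}

#' Write a fit report to JSON
#'
#' Per-start table, the optimum, convergence flags, fitted mappings and
#' all seeds/settings, serialized with full numeric precision.
#'
#' @param fit a \code{fit_result}.
#' @param path output JSON path.
#' @param alpha confidence level used for the convergence flags.
#' @export
write_fit_report <- function(fit, path, alpha = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  conv <- classify_converged(fit, alpha)
  report <- list(
    settings = list(mode = fit$mode, n_starts = fit$n_starts,
                    seed = fit$seed, alpha = alpha),
    theta_star = stats::setNames(as.list(fit$theta_star),
                                 fit$parameter_names),
    J_star = fit$J_star,
    n_converged = sum(conv),
    starts = lapply(seq_along(fit$starts), function(i) {
      s <- fit$starts[[i]]
      list(theta0 = s$theta0, theta = s$theta, J = s$J,
           grad_norm = s$grad_norm, n_evals = s$n_evals,
           converged = conv[i])
    }),
    mappings = lapply(Filter(function(sol) !is.null(sol$mapping),
                             fit$inner_star %||% list()),
                      function(sol) list(
                        observable = sol$observable_id,
                        knot_base = c(0, sol$mapping$knots),
                        knot_height = c(0, cumsum(sol$mapping$increments)),
                        sigma = sol$sigma)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write an MCMC chain to CSV
#' @param sample a \code{sample_result}.
#' @param path output CSV path.
#' @export
write_chain_csv <- function(sample, path) {
  utils::write.csv(as.data.frame(sample$chain), path, row.names = FALSE)
  invisible(path)
}

#' Write credibility bands to TSV (one file per observable)
#' @param sample a \code{sample_result}.
#' @param dir output directory.
#' @return paths written.
#' @export
write_bands_tsv <- function(sample, dir) {
  paths <- character(0)
  for (oid in names(sample$bands)) {
    p <- file.path(dir, sprintf("bands_%s.tsv", oid))
    utils::write.table(sample$bands[[oid]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
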