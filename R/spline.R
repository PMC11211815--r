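#' Monotone piecewise-linear measurement mapping
#'
#' The mapping is parameterized by uniformly spaced knot bases
#' c_1 < ... < c_n (with an implicit origin anchor c_0 = 0) and
#' nonnegative height increments xi_1, ..., xi_n: the knot heights are the
#' cumulative sums of the increments, so nonnegativity of the increments
#' makes the mapping monotone nondecreasing by construction. Between knots
#' the mapping interpolates linearly; beyond the last knot it extrapolates
#' at the constant total height; below the origin it continues the first
#' segment's slope.
#'
#' @param knots strictly increasing numeric vector of knot bases with
#'   constant spacing; first knot positive.
#' @param increments nonnegative numeric vector of height increments, same
#'   length as \code{knots}.
#' @return an object of class \code{spline_mapping}.
#' @export
spline_mapping <- function(knots, increments) {
  knots <- as.numeric(knots); increments <- as.numeric(increments)
  n <- length(knots)
  assert_that(n >= 2, "need at least 2 knots")
  assert_that(length(increments) == n, "need one increment per knot")
  d <- diff(c(0, knots))
  assert_that(all(d > 0), "knot bases must be strictly increasing and positive")
  assert_that(all(abs(d - d[1]) <= 1e-9 * d[1]), "knot spacing must be uniform")
  assert_that(all(increments >= -1e-12), "increments must be nonnegative")
  increments[increments < 0] <- 0
  structure(list(knots = knots, increments = increments, dc = d[1]),
            class = "spline_mapping")
}

#' @export
print.spline_mapping <- function(x, ...) {
  cat(sprintf("monotone piecewise-linear mapping, %d knots on [0, %.4g], total height %.4g\n",
              length(x$knots), max(x$knots), sum(x$increments)))
  invisible(x)
}

#' Uniform knot grid over the simulated range
#'
#' Places n uniformly spaced knot bases c_j = j * dc with
#' dc = (1 + margin) * max(sim_values) / n, so the grid spans from the
#' origin to a margin above the largest simulated observable value. The
#' origin anchor means the first spline branch coincides with the generic
#' branch formula, and the mapping of a zero observable is zero.
#'
#' @param sim_values finite numeric vector of simulated observable values;
#'   must have positive maximum (transform the observable otherwise).
#' @param n_knots number of knots (>= 2).
#' @param margin nonnegative fractional headroom above \code{max(sim_values)}.
#' @return numeric vector of knot bases.
#' @export
make_knot_grid <- function(sim_values, n_knots = 8, margin = 0.3) {
  assert_that(n_knots >= 2, "n_knots must be >= 2")
  assert_that(length(sim_values) > 0 && all(is.finite(sim_values)),
              "sim_values must be nonempty and finite")
  m <- max(sim_values)
  if (m <= 0)
    stop_sq(paste0("maximum simulated value is %g <= 0; the spline grid is ",
                   "anchored at the origin, so shift or transform the ",
                   "observable to be positive"), m)
  dc <- (1 + margin) * m / n_knots
  seq_len(n_knots) * dc
}

## Index of the active interval for each x under the half-open convention
## [c_{j-1}, c_j): j in 1..n, or n+1 beyond the last knot.
active_interval <- function(knots, x) {
  pmin(findInterval(x, knots) + 1L, length(knots) + 1L)
}

#' Basis matrix of the spline in its height increments
#'
#' The mapping is linear in the increments xi, so s(x_k) = sum_j B[k, j] *
#' xi_j with B[k, j] = ds(x_k)/dxi_j. Row pattern: ones left of the active
#' interval, the fractional position within it, zeros to the right; an
#' all-ones row for x beyond the last knot. This linearity is what makes
#' the inner estimation problem a convex (nonnegativity-constrained)
#' least-squares problem.
#'
#' @param mapping a \code{spline_mapping}, or a numeric vector of knot bases.
#' @param x finite numeric vector of evaluation points.
#' @return numeric matrix, \code{length(x)} rows by number-of-knots columns.
#' @export
spline_basis_matrix <- function(mapping, x) {
  knots <- if (inherits(mapping, "spline_mapping")) mapping$knots
           else as.numeric(mapping)
  n <- length(knots)
  dc <- knots[1]
  x <- as.numeric(x)
  assert_that(all(is.finite(x)), "x must be finite")
  B <- matrix(0, length(x), n)
  j <- active_interval(knots, x)
  lowed <- c(0, knots)
  for (k in seq_along(x)) {
    jk <- j[k]
    if (jk > n) {
      B[k, ] <- 1
    } else {
      if (jk > 1) B[k, seq_len(jk - 1L)] <- 1
      B[k, jk] <- (x[k] - lowed[jk]) / dc
    }
  }
  B
}

#' Evaluate the spline mapping
#'
#' @param mapping a \code{spline_mapping}.
#' @param x finite numeric scalar or vector.
#' @return mapped value(s), same length as \code{x}.
#' @export
eval_spline <- function(mapping, x) {
  stopifnot(inherits(mapping, "spline_mapping"))
  as.numeric(spline_basis_matrix(mapping, x) %*% mapping$increments)
}

#' Local slope of the spline mapping
#'
#' Returns xi_j / dc inside interval j, and 0 beyond the last knot. At a
#' knot base the right-interval slope is returned (half-open interval
#' convention), matching the basis-matrix convention so that the analytic
#' objective gradient is the exact derivative of the evaluated objective.
#'
#' @param mapping a \code{spline_mapping}.
#' @param x finite numeric scalar or vector.
#' @return slope(s), same length as \code{x}.
#' @export
spline_derivative <- function(mapping, x) {
  stopifnot(inherits(mapping, "spline_mapping"))
  x <- as.numeric(x)
  assert_that(all(is.finite(x)), "x must be finite")
  j <- active_interval(mapping$knots, x)
  n <- length(mapping$knots)
  ifelse(j > n, 0, mapping$increments[pmin(j, n)] / mapping$dc)
}

#' Linearity-promoting regularization of the spline increments
#'
#' Quadratic penalty (lambda/2) * sum_j (xi_j - mean(xi))^2, zero exactly
#' when all increments are equal, i.e. when the spline is globally linear
#' on its grid. Penalizing the spread of the increments rather than their
#' distance to a fixed slope keeps the penalty agnostic to the overall
#' scale of the mapping. Convex and quadratic in xi.
#'
#' @param increments nonnegative numeric vector.
#' @param lambda nonnegative penalty strength.
#' @return list with \code{value} and analytic \code{gradient} w.r.t. the
#'   increments.
#' @export
regularization_penalty <- function(increments, lambda) {
  assert_that(lambda >= 0, "lambda must be nonnegative")
  xi <- as.numeric(increments)
  ctr <- xi - mean(xi)
  list(value = 0.5 * lambda * sum(ctr^2), gradient = lambda * ctr)
}

#' Serialize a fitted mapping to TSV (knot_base, knot_height)
#' @param mapping a \code{spline_mapping}.
#' @param path output file path.
#' @export
write_mapping_tsv <- function(mapping, path) {
  stopifnot(inherits(mapping, "spline_mapping"))
  df <- data.frame(knot_base = c(0, mapping$knots),
                   knot_height = c(0, cumsum(mapping$increments)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mapping TSV written by \code{write_mapping_tsv}
#' @param path file path.
#' @return a \code{spline_mapping}.
#' @export
read_mapping_tsv <- function(path) {
  df <- utils::read.delim(path)
  assert_that(all(c("knot_base", "knot_height") %in% names(df)),
              "mapping TSV needs columns knot_base, knot_height")
  spline_mapping(df$knot_base[-1], diff(df$knot_height))
}
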