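#' Waterfall plot of sorted final objective values
#'
#' The standard multi-start convergence diagnostic: final objective
#' values sorted ascending; a plateau at the minimum indicates repeated
#' convergence to the same optimum.
#'
#' @param fit a \code{fit_result}.
#' @param alpha confidence level for coloring converged starts.
#' @export
plot_waterfall <- function(fit, alpha = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  J <- vapply(fit$starts, function(s) s$J, numeric(1))
  J <- J[is.finite(J)]
  conv <- classify_converged(fit, alpha)[seq_along(J)]
  graphics::plot(seq_along(J), J, pch = 19,
                 col = ifelse(conv, "forestgreen", "grey50"),
                 xlab = "sorted start index", ylab = "final objective J",
                 main = "multi-start waterfall")
  graphics::abline(h = fit$J_star + confidence_threshold(alpha,
                   length(fit$theta_star)) / 2, lty = 2, col = "red")
  invisible(fit)
}

#' Plot a fitted mapping against data and (optionally) the truth
#'
#' @param mapping a \code{spline_mapping}.
#' @param truth optional true mapping function.
#' @param y,z optional simulated inputs and measurements to overlay.
#' @export
plot_mapping <- function(mapping, truth = NULL, y = NULL, z = NULL) {
  stopifnot(inherits(mapping, "spline_mapping"))
  xs <- seq(0, max(mapping$knots), length.out = 200)
  sx <- eval_spline(mapping, xs)
  ylim <- range(sx, if (!is.null(truth)) truth(xs), z, na.rm = TRUE)
  graphics::plot(xs, sx, type = "l", lwd = 2, col = "forestgreen",
                 xlab = "model observable", ylab = "measurement scale",
                 ylim = ylim, main = "estimated measurement mapping")
  if (!is.null(truth))
    graphics::lines(xs, truth(xs), lty = 2, col = "blue", lwd = 2)
  if (!is.null(y) && !is.null(z))
    graphics::points(y, z, pch = 15, col = "steelblue")
  knot_x <- c(0, mapping$knots)
  graphics::points(knot_x, c(0, cumsum(mapping$increments)), pch = 1)
  invisible(mapping)
}

#' Plot credibility bands of the reconstructed mappings
#'
#' @param sample a \code{sample_result}.
#' @param truths optional named list of true mapping functions.
#' @export
plot_bands <- function(sample, truths = NULL) {
  stopifnot(inherits(sample, "sample_result"))
  for (oid in names(sample$bands)) {
    b <- sample$bands[[oid]]
    graphics::plot(b$x, b$median, type = "n",
                   ylim = range(b$lower, b$upper,
                                if (!is.null(truths[[oid]])) truths[[oid]](b$x)),
                   xlab = "model observable", ylab = "measurement scale",
                   main = sprintf("mapping credibility band: %s", oid))
    graphics::polygon(c(b$x, rev(b$x)), c(b$lower, rev(b$upper)),
                      col = grDevices::adjustcolor("forestgreen", 0.3),
                      border = NA)
    graphics::lines(b$x, b$median, col = "forestgreen", lwd = 2)
    if (!is.null(truths[[oid]]))
      graphics::lines(b$x, truths[[oid]](b$x), lty = 2, col = "blue", lwd = 2)
  }
  invisible(sample)
}
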