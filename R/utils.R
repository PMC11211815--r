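`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sq <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_sq(...)
  invisible(TRUE)
}

#' Normalized L2 distance between parameter vectors
#'
#' Distance metric for judging parameter-inference quality against a known
#' truth: the Euclidean norm of the difference divided by the number of
#' parameters. Computed on whatever scale the inputs are given; for kinetic
#' parameters estimated on log10 scale, pass log10 values.
#'
#' @param theta_hat estimated parameter vector.
#' @param theta_true true parameter vector, same length.
#' @return scalar, \code{||theta_hat - theta_true||_2 / length(theta_true)}.
#' @export
parameter_distance <- function(theta_hat, theta_true) {
  if (length(theta_hat) != length(theta_true))
    stop_sq("parameter_distance: length mismatch (%d vs %d)",
            length(theta_hat), length(theta_true))
  sqrt(sum((theta_hat - theta_true)^2)) / length(theta_true)
}
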