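#' Cubic B-spline basis on \[0, 1\]
#'
#' The functional basis used for the common template and the
#' participant-specific deviations: a cubic B-spline basis with `K`
#' equidistant knots on \[0, 1\] including both boundaries. With cubic order
#' this yields `K + 2` basis functions.
#'
#' @param K integer number of equidistant knots (>= 2), boundaries included.
#' @return An object of class `spline_basis` with fields `K`, `degree`,
#'   `knots` (the full, boundary-augmented knot vector) and `n_basis`.
#' @export
spline_basis <- function(K) {
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2", call. = FALSE)
  inner <- seq(0, 1, length.out = K)
  structure(
    list(K = K, degree = 3L,
         knots = c(rep(0, 3L), inner, rep(1, 3L)),
         n_basis = K + 2L),
    class = "spline_basis"
  )
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> cubic, %d equidistant knots on [0,1], %d basis functions\n",
              x$K, x$n_basis))
  invisible(x)
}

#' B-spline design matrix
#'
#' Evaluates the basis (or its time-derivative) at the given times. No
#' extrapolation: evaluation outside \[0, 1\] is an error.
#'
#' @param basis a [spline_basis()].
#' @param eval_times numeric vector in \[0, 1\].
#' @param deriv derivative order (0 = values, 1 = first derivative).
#' @return A `length(eval_times) x n_basis` matrix. Rows of the order-0
#'   design sum to 1 (partition of unity) and have at most 4 nonzero entries.
#' @export
bspline_design <- function(basis, eval_times, deriv = 0L) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(eval_times < 0 | eval_times > 1)) {
    stop("evaluation times must lie in [0, 1] (no extrapolation)", call. = FALSE)
  }
  splines::splineDesign(basis$knots, eval_times, ord = 4L,
                        derivs = rep(as.integer(deriv), length(eval_times)))
}
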