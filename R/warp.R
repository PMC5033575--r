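#' Equidistant warp anchor points
#'
#' The `n_w` anchor points of the piecewise-linear warp family:
#' `l / (n_w + 1)` for `l = 1, ..., n_w`, equidistant in the open interval
#' (0, 1).
#'
#' @param n_w number of anchors (>= 0; 0 means no warping).
#' @return Numeric vector of length `n_w`.
#' @export
warp_anchor_points <- function(n_w) {
  n_w <- as.integer(n_w)
  if (n_w < 0L) stop("`n_w` must be nonnegative", call. = FALSE)
  if (n_w == 0L) return(numeric(0))
  seq_len(n_w) / (n_w + 1)
}

#' Evaluate a piecewise-linear warp
#'
#' Evaluates the composite time warp of one repetition. The participant's
#' fixed warp is the increasing piecewise-linear interpolation through
#' `(0, 0)`, the anchor values `nu_anchors` at the equidistant anchor points,
#' and `(1, 1)`; the repetition's random deviation is the piecewise-linear
#' interpolation of the anchor deviations `w` pinned to 0 at both endpoints.
#' The composite warp is their sum, so `warp(0) = 0` and `warp(1) = 1`
#' exactly. With `n_w = 0` (empty vectors) the warp is the identity.
#'
#' @param nu_anchors participant fixed-warp values at the anchor points.
#' @param w repetition anchor deviations (same length as `nu_anchors`).
#' @param t evaluation times in \[0, 1\].
#' @return Warped times, same length as `t`.
#' @export
eval_warp <- function(nu_anchors, w, t) {
  if (length(nu_anchors) != length(w)) {
    stop("`nu_anchors` and `w` must have the same length", call. = FALSE)
  }
  if (any(t < 0 | t > 1)) stop("`t` must lie in [0, 1]", call. = FALSE)
  n_w <- length(nu_anchors)
  if (n_w == 0L) return(as.numeric(t))
  anchors <- warp_anchor_points(n_w)
  nu_part <- stats::approx(c(0, anchors, 1), c(0, nu_anchors, 1),
                           xout = t, rule = 2)$y
  dev_part <- stats::approx(c(0, anchors, 1), c(0, w, 0),
                            xout = t, rule = 2)$y
  nu_part + dev_part
}

#' Hat-function weights of the warp anchors
#'
#' Gradient of the piecewise-linear interpolation with respect to its anchor
#' values: row `k` contains the linear-interpolation (hat-function) weights
#' of the `n_w` anchors at `t[k]`. This is both the gradient of the
#' repetition warp with respect to `w` (used in the model linearization) and
#' the gradient of the fixed warp with respect to `nu_anchors`.
#'
#' @param t evaluation times in \[0, 1\].
#' @param n_w number of anchors.
#' @return A `length(t) x n_w` matrix with entries in \[0, 1\]; each row sums
#'   to at most 1.
#' @export
warp_design <- function(t, n_w) {
  if (any(t < 0 | t > 1)) stop("`t` must lie in [0, 1]", call. = FALSE)
  n_w <- as.integer(n_w)
  if (n_w == 0L) return(matrix(0, length(t), 0L))
  anchors <- warp_anchor_points(n_w)
  grid <- c(0, anchors, 1)
  H <- matrix(0, length(t), n_w)
  for (l in seq_len(n_w)) {
    e <- numeric(n_w + 2L)
    e[l + 1L] <- 1
    H[, l] <- stats::approx(grid, e, xout = t, rule = 2)$y
  }
  H
}

#' @rdname warp_design
#' @export
warp_design_row <- function(t, n_w) {
  drop(warp_design(t, n_w))
}

# Hat weight of the right boundary node (value 1 at t = 1), so that the
# composite warp can be written H %*% (nu + w) + hR.
.warp_hatR <- function(t, n_w) {
  if (n_w == 0L) return(as.numeric(t))
  anchors <- warp_anchor_points(n_w)
  e <- c(rep(0, n_w + 1L), 1)
  stats::approx(c(0, anchors, 1), e, xout = t, rule = 2)$y
}

#' Check that warp parameters define a homeomorphism
#'
#' A composite warp is admissible if the sequence 0, `nu_anchors + w`, 1 is
#' strictly increasing, i.e. the piecewise-linear map is an increasing
#' bijection of \[0, 1\] onto itself.
#'
#' @inheritParams eval_warp
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_homeomorphism <- function(nu_anchors, w) {
  if (length(nu_anchors) != length(w)) return(FALSE)
  all(diff(c(0, nu_anchors + w, 1)) > 0)
}

#' Numerically invert a piecewise-linear warp
#'
#' @inheritParams eval_warp
#' @param s warped times in \[0, 1\] to invert.
#' @return Times `t` with `eval_warp(nu_anchors, w, t) = s`.
#' @export
invert_warp <- function(nu_anchors, w, s) {
  n_w <- length(nu_anchors)
  if (n_w == 0L) return(as.numeric(s))
  if (!is_valid_homeomorphism(nu_anchors, w)) {
    stop("warp parameters do not define a homeomorphism", call. = FALSE)
  }
  anchors <- warp_anchor_points(n_w)
  stats::approx(c(0, nu_anchors + w, 1), c(0, anchors, 1), xout = s,
                rule = 2)$y
}
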