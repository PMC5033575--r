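#' Matern covariance function
#'
#' Stationary Matern covariance of the serially correlated amplitude process,
#' in the relative parametrization used throughout the model (all random
#' effects are scaled by the noise variance, so the amplitude covariance is
#' `sigma2 * matern_cov(...)`):
#' \deqn{C(d) = \tau^2 \frac{2^{1-\mu}}{\Gamma(\mu)} (\alpha d)^\mu
#'       K_\mu(\alpha d),}
#' with smoothness `mu`, relative scale `tau2` and range `1/alpha` (for
#' `mu = 1/2` this is the exponential covariance `tau2 * exp(-alpha d)`, so
#' `1/alpha` is the e-folding scale). The plain `alpha * d` convention is
#' used, not the `sqrt(2 mu)` rescaling.
#'
#' @param d numeric vector of nonnegative lags.
#' @param mu smoothness parameter, > 0.
#' @param tau2 relative scale (variance at lag 0), >= 0.
#' @param alpha inverse range, > 0.
#' @return Covariance values, same length as `d`.
#' @export
matern_cov <- function(d, mu, tau2, alpha) {
  if (any(d < 0)) stop("lags `d` must be nonnegative", call. = FALSE)
  if (mu <= 0 || alpha <= 0 || tau2 < 0) {
    stop("require mu > 0, alpha > 0, tau2 >= 0", call. = FALSE)
  }
  out <- numeric(length(d))
  zero <- d == 0
  out[zero] <- tau2
  if (any(!zero)) {
    x <- alpha * d[!zero]
    out[!zero] <- tau2 * 2^(1 - mu) / gamma(mu) * x^mu * besselK(x, mu)
  }
  out
}

#' Matern covariance matrix at observation times
#'
#' @param times numeric vector of observation times.
#' @inheritParams matern_cov
#' @return The `length(times)` square covariance matrix
#'   `matern_cov(|t_k - t_l|)`.
#' @export
matern_matrix <- function(times, mu, tau2, alpha) {
  d <- abs(outer(times, times, "-"))
  matrix(matern_cov(as.vector(d), mu, tau2, alpha), nrow = length(times))
}

#' Brownian-bridge covariance matrix at warp anchors
#'
#' Covariance of the repetition-level warp anchors: a discretely observed
#' zero-drift Brownian bridge on \[0, 1\] with relative scale `gamma2`
#' (the anchor covariance in the model is `sigma2` times this), i.e.
#' entry (k, l) is `gamma2 * min(t_k, t_l) * (1 - max(t_k, t_l))`. The bridge
#' is pinned to zero at both endpoints, encoding that timing varies most in
#' the middle of the movement.
#'
#' @param anchors strictly increasing anchor points in the open interval
#'   (0, 1).
#' @param gamma2 relative scale, >= 0.
#' @return An `n_w x n_w` symmetric matrix, positive definite for
#'   `gamma2 > 0`.
#' @export
brownian_bridge_cov <- function(anchors, gamma2) {
  if (length(anchors) == 0L) return(matrix(0, 0L, 0L))
  if (any(anchors <= 0 | anchors >= 1)) {
    stop("anchors must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(diff(anchors) <= 0)) {
    stop("anchors must be strictly increasing", call. = FALSE)
  }
  if (gamma2 < 0) stop("`gamma2` must be nonnegative", call. = FALSE)
  gamma2 * outer(anchors, anchors, function(s, t) pmin(s, t) * (1 - pmax(s, t)))
}
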