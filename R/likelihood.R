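# Core likelihood components of the hierarchical warping model:
# GLS spline updates for the template and participant deviations, the joint
# warp posterior, the model linearization in the warp parameters, and the
# linearized (Laplace-type) marginal likelihood used for variance estimation.

# Internal curve representation: drop masked points, index participants.
.prep_curves <- function(samples) {
  stopifnot(length(samples) > 0L)
  pids <- sort(unique(vapply(samples, function(s) s$participant_id, integer(1))))
  curves <- lapply(samples, function(s) {
    keep <- !s$missing_mask
    t <- s$times[keep]
    if (any(t < -1e-10 | t > 1 + 1e-10)) {
      stop("sample times must lie in [0, 1] for model fitting; ",
           "see rescale_curves()/to_percentual_time()", call. = FALSE)
    }
    list(t = pmin(pmax(t, 0), 1), y = s$values[keep],
         pi = match(s$participant_id, pids), rid = s$repetition_id)
  })
  list(curves = curves, pids = pids, np = length(pids),
       m = sum(vapply(curves, function(cv) length(cv$t), integer(1))))
}

# Lag structure of one curve's observation grid: unique lags (to 12
# significant digits) and the index map back to the full matrix. On
# (near-)equidistant grids this reduces Matern evaluation from n^2 to ~n
# Bessel calls.
.lag_info <- function(t) {
  dv <- signif(abs(outer(t, t, "-")), 12)
  ud <- unique(as.vector(dv))
  list(ud = ud, idx = match(as.vector(dv), ud), n = length(t))
}

.matern_from_lags <- function(li, mu, tau2, alpha) {
  matrix(matern_cov(li$ud, mu, tau2, alpha)[li$idx], li$n, li$n)
}

# Cholesky factors of I + S for each curve (S = Matern at observed-time
# lags); curves on identical grids share one factor.
.curve_chols <- function(curves, mu, tau2, alpha) {
  cache <- list()
  lapply(curves, function(cv) {
    key <- paste(length(cv$t), cv$t[1L], cv$t[length(cv$t)], sum(cv$t),
                 sum(cv$t^2))
    R <- cache[[key]]
    if (!is.null(R)) return(R)
    n <- length(cv$t)
    K <- diag(n)
    if (tau2 > 0) K <- K + .matern_from_lags(.lag_info(cv$t), mu, tau2, alpha)
    R <- chol(K)
    cache[[key]] <<- R
    R
  })
}

.quad_solve <- function(R, x) {
  # t(x) %*% (R'R)^{-1} %*% x via one triangular solve
  u <- backsolve(R, x, transpose = TRUE)
  if (is.matrix(u)) crossprod(u) else sum(u^2)
}

# Warped times of one curve under (nu, w), clamped to [0,1] against rounding.
.warped_times <- function(nu, w, t) {
  pmin(pmax(eval_warp(nu, w, t), 0), 1)
}

.warps_or_identity <- function(warps, prep, n_w) {
  if (is.null(warps)) {
    warps <- list(nu = matrix(rep(warp_anchor_points(n_w), each = prep$np),
                              nrow = prep$np),
                  w = matrix(0, length(prep$curves), n_w))
  }
  warps
}

#' Generalized least-squares template update
#'
#' Estimates the spline weights `c` of the common template \eqn{\theta} for
#' fixed warps, by generalized least squares with per-curve weight matrices
#' \eqn{(I + S)^{-1}}:
#' \eqn{\hat c = (\Phi^\top (I+S)^{-1}\Phi)^{-1}\Phi^\top(I+S)^{-1} y},
#' where the rows of \eqn{\Phi} are the basis functions evaluated at the
#' warped observation times. The computation exploits the block-diagonal
#' structure of \eqn{S} across curves; masked observations are dropped.
#'
#' @param samples list of [functional_sample()] with times in \[0, 1\].
#' @param basis a [spline_basis()].
#' @param warps `NULL` for identity warps, or a list with `nu` (matrix,
#'   participants in ascending id order x `n_w`) and `w` (matrix, one row per
#'   sample in `samples` order x `n_w`).
#' @param amplitude list with `mu`, `tau2`, `alpha` for the Matern amplitude
#'   covariance (relative scale; see [matern_cov()]).
#' @return Numeric vector of template weights (length `basis$n_basis`).
#' @export
estimate_template <- function(samples, basis, warps = NULL,
                              amplitude = list(mu = 1, tau2 = 0, alpha = 1)) {
  prep <- .prep_curves(samples)
  n_w <- if (is.null(warps)) 0L else ncol(warps$nu)
  warps <- .warps_or_identity(warps, prep, n_w)
  chols <- .curve_chols(prep$curves, amplitude$mu, amplitude$tau2,
                        amplitude$alpha)
  .gls_template(prep, chols, basis, warps)
}

.gls_template <- function(prep, chols, basis, warps) {
  nb <- basis$n_basis
  A <- matrix(0, nb, nb)
  b <- numeric(nb)
  for (k in seq_along(prep$curves)) {
    cv <- prep$curves[[k]]
    wt <- .warped_times(warps$nu[cv$pi, ], warps$w[k, ], cv$t)
    Phi <- bspline_design(basis, wt)
    u <- backsolve(chols[[k]], Phi, transpose = TRUE)
    v <- backsolve(chols[[k]], cv$y, transpose = TRUE)
    A <- A + crossprod(u)
    b <- b + crossprod(u, v)
  }
  ch <- tryCatch(chol(A), error = function(e) {
    stop(sprintf(
      "template design is rank deficient for K = %d knots; reduce K or add data",
      basis$K), call. = FALSE)
  })
  drop(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
}

#' Ridge-penalized participant deviation update
#'
#' Estimates the participant-specific deviation weights \eqn{d_i} for fixed
#' warps and template:
#' \eqn{\hat d_i = (\Phi_i^\top (I+S_i)^{-1}\Phi_i + \eta I)^{-1}
#'      \Phi_i^\top(I+S_i)^{-1}(y_i - \Phi_i \hat c)}.
#' The ridge weight \eqn{\eta} regularizes the deviations toward zero so the
#' common template carries as much detail as possible. With `center = TRUE`
#' the deviations are re-centered to sum to zero across participants and the
#' mean deviation is absorbed into the template weights.
#'
#' @inheritParams estimate_template
#' @param c template weights (from [estimate_template()]).
#' @param eta ridge penalty weight, >= 0 (see [eta_from_lambda()]).
#' @param center logical; re-center deviations to sum to zero and shift the
#'   template accordingly.
#' @return List with `d` (matrix, one row per participant in ascending id
#'   order) and `c` (template weights, shifted if `center = TRUE`).
#' @export
estimate_deviations <- function(samples, basis, c, warps = NULL,
                                amplitude = list(mu = 1, tau2 = 0, alpha = 1),
                                eta = 0, center = TRUE) {
  prep <- .prep_curves(samples)
  n_w <- if (is.null(warps)) 0L else ncol(warps$nu)
  warps <- .warps_or_identity(warps, prep, n_w)
  chols <- .curve_chols(prep$curves, amplitude$mu, amplitude$tau2,
                        amplitude$alpha)
  .gls_deviations(prep, chols, basis, c, warps, eta, center)
}

.gls_deviations <- function(prep, chols, basis, c, warps, eta, center = TRUE) {
  nb <- basis$n_basis
  d <- matrix(0, prep$np, nb)
  for (i in seq_len(prep$np)) {
    A <- diag(eta, nb)
    b <- numeric(nb)
    for (k in seq_along(prep$curves)) {
      cv <- prep$curves[[k]]
      if (cv$pi != i) next
      wt <- .warped_times(warps$nu[i, ], warps$w[k, ], cv$t)
      Phi <- bspline_design(basis, wt)
      u <- backsolve(chols[[k]], Phi, transpose = TRUE)
      v <- backsolve(chols[[k]], cv$y - drop(Phi %*% c), transpose = TRUE)
      A <- A + crossprod(u)
      b <- b + crossprod(u, v)
    }
    ch <- tryCatch(chol(A), error = function(e) {
      stop(sprintf(
        "deviation design is rank deficient for K = %d knots (participant %d)",
        basis$K, prep$pids[i]), call. = FALSE)
    })
    d[i, ] <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  }
  if (center && prep$np > 1L) {
    dbar <- colMeans(d)
    d <- sweep(d, 2L, dbar)
    c <- c + dbar
  }
  list(d = d, c = c)
}

#' Joint warp posterior for one participant
#'
#' The joint conditional negative log likelihood in the participant's fixed
#' warp anchors and negative log posterior of the repetition warp anchors
#' (up to an additive constant):
#' \deqn{p(\nu_i, \{w_{ij}\}) = \sum_j \|y_{ij} - (\theta+\varphi_i)\circ
#'   (\nu_i + v_{ij})(t_k)\|^2_{I+S_{ij}} + \sum_j \|w_{ij}\|^2_C,}
#' where \eqn{\|z\|^2_A = z^\top A^{-1} z}, \eqn{S_{ij}} is the Matern
#' amplitude covariance at observed-time lags and \eqn{C} the
#' Brownian-bridge anchor covariance. Warp parameters that do not define a
#' homeomorphism give `+Inf` (a barrier), distinct from numerical failure
#' which raises an error.
#'
#' @param samples_i list of [functional_sample()] for one participant.
#' @param nu_anchors participant fixed-warp anchor values (length `n_w`).
#' @param w matrix of repetition anchor deviations, one row per sample in
#'   `samples_i` order.
#' @param c template weights.
#' @param d_i participant deviation weights (same length as `c`).
#' @param basis a [spline_basis()].
#' @param amplitude list with `mu`, `tau2`, `alpha`.
#' @param gamma2 Brownian-bridge relative scale of the warp anchors.
#' @return Scalar posterior value (`+Inf` for inadmissible warps).
#' @export
warp_posterior <- function(samples_i, nu_anchors, w, c, d_i, basis,
                           amplitude = list(mu = 1, tau2 = 0, alpha = 1),
                           gamma2 = 1) {
  prep <- .prep_curves(samples_i)
  w <- as.matrix(w)
  n_w <- length(nu_anchors)
  chols <- .curve_chols(prep$curves, amplitude$mu, amplitude$tau2,
                        amplitude$alpha)
  Cinv <- if (n_w > 0L) {
    solve(brownian_bridge_cov(warp_anchor_points(n_w), gamma2))
  } else {
    matrix(0, 0L, 0L)
  }
  coef <- c + d_i
  total <- 0
  for (k in seq_along(prep$curves)) {
    if (!is_valid_homeomorphism(nu_anchors, w[k, ])) return(Inf)
    cv <- prep$curves[[k]]
    wt <- .warped_times(nu_anchors, w[k, ], cv$t)
    r <- cv$y - drop(bspline_design(basis, wt) %*% coef)
    total <- total + .quad_solve(chols[[k]], r)
    if (n_w > 0L) total <- total + drop(w[k, ] %*% Cinv %*% w[k, ])
  }
  total
}

#' Linearize the warping model in the warp anchors
#'
#' First-order Taylor expansion of the model prediction in the repetition
#' warp anchors around a prediction `w0`:
#' \eqn{y \approx \vartheta + Z(w - w^0) + x + \varepsilon}, where
#' \eqn{\vartheta} is the warped-template prediction at `w0` and each curve's
#' block of \eqn{Z} is the template time-derivative at the warped times
#' multiplied by the hat-function weights of the warp anchors
#' ([warp_design()]). The time derivative is computed analytically from the
#' spline basis; warped times are clamped to \[0, 1\].
#'
#' @inheritParams estimate_template
#' @param c template weights.
#' @param d matrix of participant deviation weights.
#' @param warps list with `nu` (matrix) and `w` (matrix, the linearization
#'   point `w0`).
#' @return List with `vartheta` (per-curve list of predictions) and `Z`
#'   (per-curve list of `m_ij x n_w` matrices).
#' @export
linearize_model <- function(samples, basis, c, d, warps) {
  prep <- .prep_curves(samples)
  n_w <- if (is.null(warps)) 0L else ncol(warps$nu)
  warps <- .warps_or_identity(warps, prep, n_w)
  vartheta <- vector("list", length(prep$curves))
  Z <- vector("list", length(prep$curves))
  for (k in seq_along(prep$curves)) {
    cv <- prep$curves[[k]]
    coef <- c + d[cv$pi, ]
    wt <- .warped_times(warps$nu[cv$pi, ], warps$w[k, ], cv$t)
    vartheta[[k]] <- drop(bspline_design(basis, wt) %*% coef)
    deriv <- drop(bspline_design(basis, wt, deriv = 1L) %*% coef)
    Z[[k]] <- deriv * warp_design(cv$t, n_w)
  }
  list(vartheta = vartheta, Z = Z)
}

#' Linearized marginal negative log likelihood
#'
#' Twice the negative profile log likelihood of the linearized model
#' (dropping the `m log 2*pi` constant):
#' \deqn{\ell(\sigma^2, C, S) = m \log\sigma^2 + \log\det V +
#'   \sigma^{-2}\, \| y - \vartheta + Z w^0 \|^2_V,}
#' with \eqn{V = S + Z (I \otimes C) Z^\top + I_m}. Because the warp anchors
#' of different curves are independent, \eqn{V} is block diagonal over
#' curves; each block is factorized by Cholesky and the full `m x m` matrix
#' is never formed.
#'
#' @inheritParams estimate_template
#' @param linearization output of [linearize_model()] (`vartheta`, `Z`).
#' @param w0 matrix of linearization-point anchor predictions (one row per
#'   sample).
#' @param sigma2 noise variance.
#' @param gamma2 Brownian-bridge relative scale.
#' @return Scalar value of the criterion.
#' @export
linearized_nll <- function(samples, linearization, w0, sigma2,
                           amplitude = list(mu = 1, tau2 = 0, alpha = 1),
                           gamma2 = 1) {
  prep <- .prep_curves(samples)
  w0 <- as.matrix(w0)
  n_w <- ncol(w0)
  C <- if (n_w > 0L) brownian_bridge_cov(warp_anchor_points(n_w), gamma2)
       else matrix(0, 0L, 0L)
  parts <- .nll_blocks(prep, linearization, w0, C, amplitude)
  prep$m * log(sigma2) + parts$logdet + parts$quad / sigma2
}

# Shared block computation: log det V and the V-quadratic form.
# `laginfos` (optional) are precomputed lag structures per curve. Curves
# observed on identical grids share one Matern block, which is built once.
.nll_blocks <- function(prep, linearization, w0, C, amplitude,
                        laginfos = NULL) {
  logdet <- 0
  quad <- 0
  grid_keys <- vapply(prep$curves, function(cv)
    paste(length(cv$t), cv$t[1L], cv$t[length(cv$t)], sum(cv$t),
          sum(cv$t^2)), character(1))
  S_cache <- list()
  for (k in seq_along(prep$curves)) {
    cv <- prep$curves[[k]]
    Zk <- linearization$Z[[k]]
    n <- length(cv$t)
    if (amplitude$tau2 > 0) {
      key <- grid_keys[k]
      S <- S_cache[[key]]
      if (is.null(S)) {
        li <- if (is.null(laginfos)) .lag_info(cv$t) else laginfos[[k]]
        S <- .matern_from_lags(li, amplitude$mu, amplitude$tau2,
                               amplitude$alpha)
        S_cache[[key]] <- S
      }
    } else {
      S <- matrix(0, n, n)
    }
    V <- S + diag(n)
    if (ncol(Zk) > 0L) V <- V + Zk %*% C %*% t(Zk)
    R <- tryCatch(chol(V), error = function(e) {
      stop(sprintf("marginal covariance block %d is not positive definite", k),
           call. = FALSE)
    })
    r <- cv$y - linearization$vartheta[[k]]
    if (ncol(Zk) > 0L) r <- r + drop(Zk %*% w0[k, ])
    logdet <- logdet + 2 * sum(log(diag(R)))
    quad <- quad + .quad_solve(R, r)
  }
  list(logdet = logdet, quad = quad)
}

#' Normalized ridge weight
#'
#' The participant-deviation penalty weight normalized by the variance of
#' the amplitude effects, `eta = lambda / (1 + tau2)`, so the penalty acts
#' consistently across conditions with different amplitude variances.
#'
#' @param lambda raw penalty weight, >= 0.
#' @param tau2 relative amplitude scale, >= 0.
#' @return `lambda / (1 + tau2)`.
#' @export
eta_from_lambda <- function(lambda, tau2) {
  if (lambda < 0 || tau2 < 0) {
    stop("`lambda` and `tau2` must be nonnegative", call. = FALSE)
  }
  lambda / (1 + tau2)
}
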