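# Synthetic-data generators for both models, so every stage of the
# pipeline is testable end to end. The generators return the complete
# latent ground truth alongside the data, so recovery metrics can be
# computed without re-deriving anything.

# Symmetric square root via eigendecomposition (handles PSD matrices with
# zero eigenvalues, unlike Cholesky).
.mat_sqrt <- function(S) {
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
}

#' Default double-bump template weights
#'
#' Spline weights of a smooth double-bump acceleration-like profile on
#' \[0, 1\] (two positive bumps of unequal height), obtained by projecting
#' a fixed Gaussian-bump mixture onto the basis. Stored as weights so GLS
#' template estimation can represent the truth exactly.
#'
#' @param basis a [spline_basis()].
#' @return Numeric vector of length `basis$n_basis`.
#' @export
template_weights_double_bump <- function(basis) {
  g <- seq(0, 1, length.out = 400L)
  f <- exp(-((g - 0.32) / 0.1)^2) + 0.75 * exp(-((g - 0.7) / 0.09)^2)
  Phi <- bspline_design(basis, g)
  drop(qr.coef(qr(Phi), f))
}

#' Simulate curves from the hierarchical warping model
#'
#' Draws repeated functional observations from the generative model: a
#' common spline template plus participant deviations, composed with
#' piecewise-linear warps (participant fixed anchors plus repetition
#' anchors drawn from the Brownian-bridge prior, redrawn on the rare event
#' that they violate monotonicity), plus a Matern amplitude process (exact
#' multivariate normal via Cholesky factorization of the covariance) and
#' white observation noise. All random-effect scales follow the model's
#' convention of being relative to the noise standard deviation: the warp
#' anchors have covariance `sigma2 * gamma2 * C_bridge` and the amplitude
#' process has variance `sigma2 * tau2`.
#'
#' Defaults mirror the scale of a single experimental condition of a
#' desk-size movement study: 10 participants with 10 repetitions of 50
#' observed time points each.
#'
#' @param n_participants,n_repetitions,n_timepoints design sizes (all >= 1).
#' @param K template spline knots.
#' @param n_w number of warp anchors (0 = no warping).
#' @param sigma2 noise variance.
#' @param tau2,alpha,mu Matern amplitude parameters (relative scale,
#'   inverse range, smoothness).
#' @param gamma2 Brownian-bridge relative scale of the repetition warps.
#' @param nu_sd standard deviation of the participant fixed-warp anchor
#'   values around the identity (participant-level timing variation).
#' @param phi_sd coefficient-scale standard deviation of the smooth
#'   participant template deviations (centered across participants).
#' @param template template weights; defaults to
#'   [template_weights_double_bump()].
#' @param d optional fixed matrix of participant deviation weights
#'   (overrides `phi_sd`).
#' @param nu optional fixed matrix of participant warp anchor values
#'   (overrides `nu_sd`).
#' @param seed integer seed; fixed seed gives identical output.
#' @return List with `samples` (list of [functional_sample()], times on a
#'   common equidistant grid in \[0, 1\]) and `truth` (all latent values
#'   and parameters: `c`, `d`, `nu`, `w`, `x`, plus the generating
#'   parameters).
#' @export
simulate_curves <- function(n_participants = 10L, n_repetitions = 10L,
                            n_timepoints = 50L, K = 12L, n_w = 2L,
                            sigma2 = 1e-4, tau2 = 1, alpha = 5, mu = 1,
                            gamma2 = 0.25, nu_sd = 0.02, phi_sd = 0.05,
                            template = NULL, d = NULL, nu = NULL,
                            seed = NULL) {
  stopifnot(n_participants >= 1L, n_repetitions >= 1L, n_timepoints >= 3L)
  if (!is.null(seed)) set.seed(seed)
  basis <- spline_basis(K)
  if (is.null(template)) template <- template_weights_double_bump(basis)
  stopifnot(length(template) == basis$n_basis)
  anchors <- warp_anchor_points(n_w)
  tgrid <- seq(0, 1, length.out = n_timepoints)

  if (is.null(d)) {
    d <- matrix(stats::rnorm(n_participants * basis$n_basis, sd = phi_sd),
                n_participants)
    if (n_participants > 1L) d <- sweep(d, 2L, colMeans(d))
  }
  stopifnot(nrow(d) == n_participants, ncol(d) == basis$n_basis)

  # participant fixed warps: identity anchors plus bounded jitter
  if (!is.null(nu)) {
    nu <- as.matrix(nu)
    stopifnot(nrow(nu) == n_participants, ncol(nu) == n_w)
    nu_sd <- 0
  } else {
    nu <- matrix(rep(anchors, each = n_participants), n_participants)
  }
  if (n_w > 0L && nu_sd > 0) {
    repeat {
      cand <- nu + matrix(stats::rnorm(length(nu), sd = nu_sd),
                          n_participants)
      ok <- all(apply(cand, 1L, function(v) all(diff(c(0, v, 1)) > 0)))
      if (ok) {
        nu <- cand
        break
      }
    }
  }

  Cw <- if (n_w > 0L) sigma2 * gamma2 *
    brownian_bridge_cov(anchors, 1) else NULL
  Lw <- if (n_w > 0L && gamma2 > 0 && sigma2 > 0) chol(Cw) else NULL
  Sx <- sigma2 * matern_matrix(tgrid, mu, tau2, alpha)
  Lx <- if (tau2 > 0 && sigma2 > 0) .mat_sqrt(Sx) else NULL

  samples <- vector("list", n_participants * n_repetitions)
  w_all <- matrix(0, n_participants * n_repetitions, n_w)
  x_all <- matrix(0, n_participants * n_repetitions, n_timepoints)
  k <- 0L
  for (i in seq_len(n_participants)) {
    for (j in seq_len(n_repetitions)) {
      k <- k + 1L
      w <- rep(0, n_w)
      if (!is.null(Lw)) {
        repeat {
          w <- drop(stats::rnorm(n_w) %*% Lw)
          if (is_valid_homeomorphism(nu[i, ], w)) break
        }
      }
      wt <- .warped_times(nu[i, ], w, tgrid)
      signal <- drop(bspline_design(basis, wt) %*% (template + d[i, ]))
      x <- if (is.null(Lx)) rep(0, n_timepoints)
           else drop(stats::rnorm(n_timepoints) %*% Lx)
      eps <- if (sigma2 > 0) stats::rnorm(n_timepoints, sd = sqrt(sigma2))
             else rep(0, n_timepoints)
      w_all[k, ] <- w
      x_all[k, ] <- x
      samples[[k]] <- functional_sample(i, j, "sim", tgrid, signal + x + eps)
    }
  }
  list(samples = samples,
       truth = list(c = template, d = d, nu = nu, w = w_all, x = x_all,
                    basis = basis, n_w = n_w, sigma2 = sigma2, tau2 = tau2,
                    alpha = alpha, mu = mu, gamma2 = gamma2))
}

#' Default reference path for trajectory simulation
#'
#' A smooth 30 x 3 arc qualitatively resembling an object transport over an
#' obstacle: forward progress in x, a lateral excursion in y and an
#' elevation bump in z (cm).
#'
#' @return A 30 x 3 matrix.
#' @export
default_reference_path <- function() {
  tt <- seq(0, 1, length.out = 30L)
  cbind(40 * tt, 4 * sin(pi * tt), 12 * sin(pi * tt)^2)
}

#' Default orthonormal loading matrix
#'
#' A deterministic orthonormal 90 x q loading matrix built from smooth
#' sinusoidal patterns in the three coordinates (QR-orthonormalized).
#'
#' @param q number of loadings.
#' @return A 90 x q matrix with orthonormal columns.
#' @export
default_loadings <- function(q) {
  tt <- seq(0, 1, length.out = 30L)
  raw <- sapply(seq_len(q), function(k) {
    coord <- (k - 1L) %% 3L + 1L
    pattern <- sin(pi * ceiling(k / 3) * tt + 0.3 * k)
    path <- matrix(0, 30L, 3L)
    path[, coord] <- pattern
    path[, (coord %% 3L) + 1L] <- 0.3 * cos(pi * k * tt)
    .fa_vec(path)
  })
  qr.Q(qr(raw))[, seq_len(q), drop = FALSE]
}

#' Simulate aligned trajectories from the factor model
#'
#' Draws 30 x 3 aligned movement paths from the mixed-effects factor model:
#' participant latent effects shared across all of a participant's curves,
#' height-reaction effects shared within participant-by-height cells,
#' repetition effects independent per curve, a covariate effect of obstacle
#' height along the loadings, and per-coordinate white noise.
#'
#' @param n_participants,n_repetitions design sizes (3 height levels are
#'   always generated).
#' @param q number of loadings.
#' @param W orthonormal 90 x q loading matrix; defaults to
#'   [default_loadings()]. A non-orthonormal `W` is a configuration error.
#' @param beta covariate weights, `p x q` with p matching the design.
#' @param design `"anova"` or `"regression"` (see [fit_factor_model()]).
#' @param Sigma list of three q x q level covariances (participant,
#'   height reaction, repetition).
#' @param Lambda length-3 noise variances (one per spatial coordinate).
#' @param theta 30 x 3 reference path; defaults to
#'   [default_reference_path()].
#' @param distance_cm metadata attached to each trajectory.
#' @param seed integer seed.
#' @return List with `trajectories` (list of [trajectory_sample()]) and
#'   `truth` (generating parameters and all latent draws).
#' @export
simulate_trajectories <- function(n_participants = 10L, n_repetitions = 10L,
                                  q = 3L, W = NULL, beta = NULL,
                                  design = c("anova", "regression"),
                                  Sigma = NULL, Lambda = c(0.04, 0.04, 0.04),
                                  theta = NULL, distance_cm = 30,
                                  seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(W)) W <- default_loadings(q)
  if (max(abs(crossprod(W) - diag(ncol(W)))) > 1e-8) {
    stop("`W` must have orthonormal columns", call. = FALSE)
  }
  q <- ncol(W)
  X_levels <- .fa_design_levels(design)
  p <- ncol(X_levels)
  if (is.null(beta)) {
    beta <- matrix(0, p, q)
    base <- c(3, 1.2, 0.5, rep(0.2, max(0, q - 3L)))[seq_len(q)]
    if (design == "anova") {
      beta[1L, ] <- 0.5 * base
      beta[2L, ] <- base
    } else {
      beta[1L, ] <- base / 15
    }
  }
  stopifnot(nrow(beta) == p, ncol(beta) == q)
  if (is.null(Sigma)) {
    Sigma <- list(diag(2.0, q), diag(0.3, q), diag(0.8, q))
  }
  if (is.null(theta)) theta <- default_reference_path()
  theta_vec <- .fa_vec(theta)
  chols <- lapply(Sigma, .mat_sqrt)
  lam90 <- Lambda[.fa_dim_idx]

  trajectories <- list()
  z1_all <- matrix(0, n_participants, q)
  z2_all <- array(0, c(n_participants, 3L, q))
  z3_all <- list()
  k <- 0L
  for (i in seq_len(n_participants)) {
    z1 <- drop(stats::rnorm(q) %*% chols[[1L]])
    z1_all[i, ] <- z1
    for (h in 1:3) {
      z2 <- drop(stats::rnorm(q) %*% chols[[2L]])
      z2_all[i, h, ] <- z2
      for (j in seq_len(n_repetitions)) {
        k <- k + 1L
        z3 <- drop(stats::rnorm(q) %*% chols[[3L]])
        z3_all[[k]] <- z3
        score <- drop(X_levels[h, , drop = FALSE] %*% beta) + z1 + z2 + z3
        yv <- theta_vec + drop(W %*% score) +
          stats::rnorm(90L, sd = sqrt(lam90))
        trajectories[[k]] <- trajectory_sample(
          i, j, h, matrix(yv, 30L, 3L, byrow = TRUE), distance_cm)
      }
    }
  }
  list(trajectories = trajectories,
       truth = list(W = W, beta = beta, Sigma = Sigma, Lambda = Lambda,
                    theta = theta, design = design, z1 = z1_all, z2 = z2_all,
                    z3 = do.call(rbind, z3_all)))
}
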