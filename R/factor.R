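# Mixed-effects factor analysis of temporally aligned 30 x 3 movement
# paths: a low-rank loading structure with an obstacle-height covariate
# design and three nested Gaussian random-effect levels (participant,
# participant x height reaction, repetition), fitted by ECM with SQUAREM
# acceleration.
#
# Trajectories are vectorized time-major with the coordinate index fastest
# (30 time points x 3 coordinates -> 90-vector), and the noise covariance
# has one variance parameter per spatial coordinate.

.fa_dim_idx <- rep(1:3, 30)

.fa_design_levels <- function(design) {
  switch(design,
    anova = rbind(c(0, 0), c(1, 0), c(0, 1)),
    regression = matrix(c(0, 7.5, 15), ncol = 1L),
    stop("unknown design: ", design, call. = FALSE))
}

.fa_vec <- function(path) as.vector(t(path))

.fa_data <- function(trajectories, design, reference = 1L, theta = NULL) {
  stopifnot(length(trajectories) > 0L)
  Y <- do.call(rbind, lapply(trajectories, function(s) .fa_vec(s$path)))
  pid <- vapply(trajectories, function(s) s$participant_id, integer(1))
  height <- vapply(trajectories, function(s) s$height_level, integer(1))
  if (!any(height == reference)) {
    stop("no trajectories at the reference height level", call. = FALSE)
  }
  X_levels <- .fa_design_levels(design)
  theta <- if (is.null(theta)) {
    colMeans(Y[height == reference, , drop = FALSE])
  } else {
    .fa_vec(as.matrix(theta))
  }
  list(Y = Y, pid = pid, height = height, n = nrow(Y),
       X = X_levels[height, , drop = FALSE], X_levels = X_levels,
       theta = theta, design = design, reference = reference,
       participants = sort(unique(pid)))
}

# One E-step (log likelihood + posterior moments) and, if `update = TRUE`,
# the full ECM parameter update. Returns list(loglik, params).
.fa_estep <- function(params, dat, update = TRUE) {
  q <- ncol(params$W)
  W <- params$W
  lam90 <- params$Lambda[.fa_dim_idx]
  Wl <- W / lam90
  G <- crossprod(W, Wl)
  inv_S <- lapply(params$Sigma, function(S) chol2inv(chol(S)))
  logdet_S <- vapply(params$Sigma, function(S) {
    2 * sum(log(diag(chol(S))))
  }, numeric(1))
  theta_row <- matrix(dat$theta, 1L, length(dat$theta))

  loglik <- 0
  n <- dat$n
  A_all <- matrix(0, n, q)      # posterior mean of summed latent effects
  Vsum <- matrix(0, q, q)       # sum over curves of A_c Cov A_c'
  S1 <- matrix(0, q, q); S2 <- matrix(0, q, q); S3 <- matrix(0, q, q)
  N2 <- 0L
  Sxx <- matrix(0, ncol(dat$X), ncol(dat$X))
  Brhs <- matrix(0, ncol(dat$X), q)

  for (p in dat$participants) {
    idx <- which(dat$pid == p)
    n_c <- length(idx)
    hh <- dat$height[idx]
    uh <- sort(unique(hh))
    nb <- 1L + length(uh) + n_c
    # incidence of curves on latent blocks: participant, height group, rep
    Ainc <- matrix(0, n_c, nb)
    Ainc[, 1L] <- 1
    for (cix in seq_len(n_c)) {
      Ainc[cix, 1L + match(hh[cix], uh)] <- 1
      Ainc[cix, 1L + length(uh) + cix] <- 1
    }
    Yi <- dat$Y[idx, , drop = FALSE]
    Y0 <- Yi - theta_row[rep(1L, n_c), , drop = FALSE]
    mean_fix <- (dat$X[idx, , drop = FALSE] %*% params$beta) %*% t(W)
    Rm <- Y0 - mean_fix
    Ytil <- Rm %*% Wl                      # n_c x q
    rhs_mat <- crossprod(Ainc, Ytil)       # nb x q
    rhs <- as.vector(t(rhs_mat))

    P0inv_blocks <- c(list(inv_S[[1L]]),
                      rep(list(inv_S[[2L]]), length(uh)),
                      rep(list(inv_S[[3L]]), n_c))
    Om <- kronecker(crossprod(Ainc), G)
    for (b in seq_len(nb)) {
      rows <- ((b - 1L) * q + 1L):(b * q)
      Om[rows, rows] <- Om[rows, rows] + P0inv_blocks[[b]]
    }
    cholOm <- chol(Om)
    Cov <- chol2inv(cholOm)
    mu_u <- drop(Cov %*% rhs)

    rDr <- sum(sweep(Rm^2, 2L, lam90, "/"))
    logdet_P0 <- logdet_S[1L] + length(uh) * logdet_S[2L] + n_c * logdet_S[3L]
    loglik <- loglik - 0.5 * (
      n_c * 90 * log(2 * pi) + n_c * 30 * sum(log(params$Lambda)) +
      logdet_P0 + 2 * sum(log(diag(cholOm))) + rDr - sum(rhs * mu_u))

    if (!update) next

    mu_mat <- matrix(mu_u, nb, q, byrow = TRUE)  # block means as rows
    # per-curve summed latent means: A_c u = sum of the curve's 3 blocks
    A_all[idx, ] <- Ainc %*% mu_mat
    # sum over curves of A_c Cov A_c' via one tensor contraction:
    # Vsum += sum_{b1,b2} (Ainc'Ainc)[b1,b2] CovBlock[b1,b2]
    Cov4 <- array(Cov, c(q, nb, q, nb))
    Cflat <- matrix(aperm(Cov4, c(1L, 3L, 2L, 4L)), q * q, nb * nb)
    Vsum <- Vsum + matrix(Cflat %*% as.vector(crossprod(Ainc)), q, q)
    # block-diagonal covariance blocks (for the level covariance updates)
    bdiag_sum <- function(bs) {
      out <- matrix(0, q, q)
      for (b in bs) {
        rows <- ((b - 1L) * q + 1L):(b * q)
        out <- out + Cov[rows, rows]
      }
      out
    }
    b2 <- 1L + seq_along(uh)
    b3 <- 1L + length(uh) + seq_len(n_c)
    S1 <- S1 + tcrossprod(mu_mat[1L, ]) + Cov[1:q, 1:q, drop = FALSE]
    S2 <- S2 + crossprod(mu_mat[b2, , drop = FALSE]) + bdiag_sum(b2)
    S3 <- S3 + crossprod(mu_mat[b3, , drop = FALSE]) + bdiag_sum(b3)
    N2 <- N2 + length(uh)
    # pieces for the covariate-weight update
    Ytil0 <- Y0 %*% Wl
    H <- Ytil0 - A_all[idx, , drop = FALSE] %*% G
    Brhs <- Brhs + crossprod(dat$X[idx, , drop = FALSE], H)
    Sxx <- Sxx + crossprod(dat$X[idx, , drop = FALSE])
  }

  if (!update) return(list(loglik = loglik, params = params))

  beta_new <- solve(Sxx, Brhs) %*% chol2inv(chol(G))
  Sigma_new <- list(.fa_sym(S1 / length(dat$participants)),
                    .fa_sym(S2 / N2),
                    .fa_sym(S3 / n))
  Ms <- dat$X %*% beta_new + A_all               # n x q, E[s_c]
  Y0_all <- dat$Y - theta_row[rep(1L, n), , drop = FALSE]
  E_mat <- Y0_all - Ms %*% t(W)
  total90 <- colSums(E_mat^2) + rowSums((W %*% Vsum) * W)
  Lambda_new <- vapply(1:3, function(dd) {
    sum(total90[.fa_dim_idx == dd]) / (30 * n)
  }, numeric(1))
  Lambda_new <- pmax(Lambda_new, 1e-12)
  M <- crossprod(Ms) + Vsum
  W_new <- crossprod(Y0_all, Ms) %*% chol2inv(chol(.fa_sym(M)))

  list(loglik = loglik,
       params = list(beta = beta_new, Sigma = Sigma_new,
                     Lambda = Lambda_new, W = W_new))
}

.fa_sym <- function(S) (S + t(S)) / 2

# Project a symmetric matrix to the PSD cone (eigenvalue clipping).
.fa_psd <- function(S, floor = 1e-10) {
  S <- .fa_sym(S)
  ee <- eigen(S, symmetric = TRUE)
  if (min(ee$values) >= floor) return(S)
  ee$vectors %*% (pmax(ee$values, floor) * t(ee$vectors))
}

.fa_pack <- function(p) {
  c(as.vector(p$beta), unlist(lapply(p$Sigma, as.vector)),
    log(p$Lambda), as.vector(p$W))
}

.fa_unpack <- function(v, tmpl) {
  q <- ncol(tmpl$W)
  pdim <- nrow(tmpl$beta)
  i <- 0L
  take <- function(k) {
    out <- v[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  beta <- matrix(take(pdim * q), pdim, q)
  Sigma <- lapply(1:3, function(l) .fa_psd(matrix(take(q * q), q, q)))
  Lambda <- pmax(exp(take(3L)), 1e-12)
  W <- matrix(take(90L * q), 90L, q)
  list(beta = beta, Sigma = Sigma, Lambda = Lambda, W = W)
}

.fa_init <- function(dat, q) {
  Y0 <- sweep(dat$Y, 2L, dat$theta)
  if (q > min(dim(Y0))) stop("`q` exceeds the data dimension", call. = FALSE)
  sv <- svd(Y0, nu = 0, nv = q)
  if (sv$d[q] < 1e-10 * sv$d[1L] && sv$d[1L] > 0) {
    stop("`q` exceeds the numerical rank of the data", call. = FALSE)
  }
  W <- sv$v[, seq_len(q), drop = FALSE]
  scores <- Y0 %*% W
  beta <- solve(crossprod(dat$X) + 1e-10 * diag(ncol(dat$X)),
                crossprod(dat$X, scores))
  rs <- scores - dat$X %*% beta
  v <- pmax(apply(rs, 2L, stats::var), 1e-6)
  E0 <- Y0 - scores %*% t(W)
  Lambda <- vapply(1:3, function(dd) {
    max(mean(E0[, .fa_dim_idx == dd]^2), 1e-8)
  }, numeric(1))
  list(beta = beta,
       Sigma = lapply(1:3, function(l) diag(v / 3, q)),
       Lambda = Lambda, W = W)
}

#' Fit the mixed-effects factor model for aligned movement paths
#'
#' Maximum-likelihood estimation of the factor model
#' \eqn{y_{ijh} = \theta + (X_h\beta + \sum_{l=1}^3 Z_{i,g_l(j,h),l})
#' W^\top + \varepsilon_{ij}}: a fixed reference path \eqn{\theta} (the
#' pointwise mean trajectory of the reference obstacle height), `q`
#' loadings spanning the subspace of path variation, a covariate design in
#' obstacle height (two-parameter ANOVA encoding or one-parameter linear
#' regression in height increase 0 / 7.5 / 15), and three nested Gaussian
#' random-effect levels: participant, participant-by-height reaction, and
#' repetition, each with its own q x q covariance. The noise has one
#' variance per spatial coordinate.
#'
#' Fitting uses an ECM algorithm (E-step: posterior moments of all latent
#' level effects; CM-steps: covariate weights, level covariances, noise
#' variances, loadings) accelerated by SQUAREM squared extrapolation with a
#' monotonicity safeguard: an extrapolated step that would decrease the log
#' likelihood (or leave the parameter space, after projection back to it)
#' is rejected in favor of the plain ECM step. The returned model is
#' identified via [identify_loadings()].
#'
#' @param trajectories list of [trajectory_sample()] objects.
#' @param q number of loadings (1 <= q <= 90, at most the data rank).
#' @param design `"anova"` (height levels S/M/T coded (0,0), (1,0), (0,1))
#'   or `"regression"` (height increase 0, 7.5, 15 cm).
#' @param reference height level whose mean path is the fixed reference
#'   \eqn{\theta} (default 1, the lowest obstacle).
#' @param theta optional 30 x 3 matrix fixing the reference path directly
#'   (otherwise the pointwise mean of the reference-height trajectories is
#'   used).
#' @param max_iter maximum number of ECM map applications.
#' @param tol relative log-likelihood change declaring convergence.
#' @param squarem logical; use SQUAREM acceleration.
#' @param init optional list of starting parameters (`beta`, `Sigma`,
#'   `Lambda`, `W`).
#' @param identify logical; return the identified parametrization.
#' @return An object of class `factor_model` with elements `theta` (30 x 3),
#'   `W`, `beta`, `Sigma` (list of 3), `Lambda`, `design`, `X_levels`, `q`,
#'   `loglik`, `trace` (accepted log-likelihood values, nondecreasing),
#'   `converged` and `n_iter`.
#' @export
fit_factor_model <- function(trajectories, q, design = c("anova", "regression"),
                             reference = 1L, max_iter = 500L, tol = 1e-9,
                             squarem = TRUE, init = NULL, identify = TRUE,
                             theta = NULL) {
  design <- match.arg(design)
  dat <- .fa_data(trajectories, design, reference, theta = theta)
  params <- if (is.null(init)) .fa_init(dat, q) else init
  q <- ncol(params$W)

  n_iter <- 0L
  warned_psd <- FALSE
  Fmap <- function(p) {
    n_iter <<- n_iter + 1L
    .fa_estep(p, dat, update = TRUE)
  }
  ll_of <- function(p) .fa_estep(p, dat, update = FALSE)$loglik

  trace <- numeric(0)
  converged <- FALSE
  ll_cycle_prev <- -Inf
  p0 <- params

  while (n_iter < max_iter) {
    s1 <- Fmap(p0)                      # loglik at p0, params p1
    p1 <- s1$params
    trace <- c(trace, s1$loglik)
    # compare across cycle boundaries only (>= 1 EM step apart)
    if (is.finite(ll_cycle_prev) &&
        abs(s1$loglik - ll_cycle_prev) < tol * (abs(s1$loglik) + 1)) {
      converged <- TRUE
      p0 <- p1
      break
    }
    ll_cycle_prev <- s1$loglik
    if (!squarem || n_iter + 2L > max_iter) {
      p0 <- p1
      next
    }
    s2 <- Fmap(p1)
    p2 <- s2$params
    trace <- c(trace, s2$loglik)
    v0 <- .fa_pack(p0); v1 <- .fa_pack(p1); v2 <- .fa_pack(p2)
    r <- v1 - v0
    vv <- v2 - 2 * v1 + v0
    if (sqrt(sum(vv^2)) < 1e-14) {
      p0 <- p2
      next
    }
    alpha <- -sqrt(sum(r^2) / sum(vv^2))
    if (!is.finite(alpha) || alpha > -1) alpha <- -1
    cand <- tryCatch(.fa_unpack(v0 - 2 * alpha * r + alpha^2 * vv, p0),
                     error = function(e) NULL)
    if (is.null(cand)) {
      p0 <- p2
      next
    }
    sc <- tryCatch(Fmap(cand), error = function(e) NULL)
    ll2 <- ll_of(p2)
    if (!is.null(sc) && is.finite(sc$loglik) && sc$loglik >= ll2 - 1e-10) {
      p0 <- sc$params
      trace <- c(trace, sc$loglik)
    } else {
      p0 <- p2
    }
  }

  final_ll <- ll_of(p0)
  trace <- c(trace, final_ll)
  model <- structure(
    list(theta = matrix(dat$theta, 30L, 3L, byrow = TRUE),
         W = p0$W, beta = p0$beta, Sigma = p0$Sigma, Lambda = p0$Lambda,
         design = design, X_levels = dat$X_levels, q = q,
         reference = reference, loglik = final_ll, trace = trace,
         converged = converged, n_iter = n_iter),
    class = "factor_model"
  )
  if (identify) identify_loadings(model) else model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "<factor_model> q = %d, %s design\n  loglik = %.4f after %d ECM steps (converged: %s)\n  noise variances: %s\n",
    x$q, x$design, x$loglik, x$n_iter, x$converged,
    paste(signif(x$Lambda, 4), collapse = ", ")))
  invisible(x)
}

#' Log likelihood of a factor model on data
#'
#' Evaluates the marginal Gaussian log likelihood of a (fitted or
#' constructed) `factor_model` on a set of trajectories, using the model's
#' stored reference path.
#'
#' @param model a `factor_model`.
#' @param trajectories list of [trajectory_sample()] objects.
#' @return Scalar log likelihood.
#' @export
factor_model_loglik <- function(model, trajectories) {
  dat <- .fa_data(trajectories, model$design, model$reference)
  dat$theta <- .fa_vec(model$theta)
  params <- list(beta = model$beta, Sigma = model$Sigma,
                 Lambda = model$Lambda, W = model$W)
  .fa_estep(params, dat, update = FALSE)$loglik
}

#' Identify the loading matrix
#'
#' Applies the two-stage identification of the loadings: first the scaling
#' is fixed by orthonormalizing `W` (symmetric orthonormalization, so an
#' already-orthonormal `W` is unchanged); second the rotation is fixed by
#' diagonalizing the total latent covariance of a single curve,
#' \eqn{\sum_l \Sigma_l}, with the diagonal sorted in decreasing order.
#' Column signs are fixed so the largest-magnitude entry of each loading is
#' positive. The covariate weights and level covariances are co-transformed
#' so the likelihood is unchanged; the map is idempotent.
#'
#' @param model a `factor_model`.
#' @return The identified `factor_model`.
#' @export
identify_loadings <- function(model) {
  q <- model$q
  W <- model$W
  # scale: W <- W (W'W)^{-1/2}, latent s <- (W'W)^{1/2} s
  ee <- eigen(.fa_sym(crossprod(W)), symmetric = TRUE)
  if (min(ee$values) <= 0) stop("loading matrix is rank deficient", call. = FALSE)
  Thalf <- ee$vectors %*% (sqrt(ee$values) * t(ee$vectors))
  Thalf_inv <- ee$vectors %*% ((1 / sqrt(ee$values)) * t(ee$vectors))
  W <- W %*% Thalf_inv
  beta <- model$beta %*% Thalf
  Sigma <- lapply(model$Sigma, function(S) .fa_sym(Thalf %*% S %*% Thalf))
  # rotation: diagonalize the total latent covariance, decreasing diagonal
  tot <- .fa_sym(Reduce(`+`, Sigma))
  eq <- eigen(tot, symmetric = TRUE)
  Q <- eq$vectors
  W <- W %*% Q
  beta <- beta %*% Q
  Sigma <- lapply(Sigma, function(S) .fa_sym(t(Q) %*% S %*% Q))
  # deterministic column signs
  for (k in seq_len(q)) {
    if (W[which.max(abs(W[, k])), k] < 0) {
      W[, k] <- -W[, k]
      beta[, k] <- -beta[, k]
      for (l in 1:3) {
        Sigma[[l]][k, ] <- -Sigma[[l]][k, ]
        Sigma[[l]][, k] <- -Sigma[[l]][, k]
      }
    }
  }
  model$W <- W
  model$beta <- beta
  model$Sigma <- Sigma
  model
}

#' Per-loading percentage of variance explained
#'
#' Decomposes the total fitted variance of a single trajectory into the
#' contribution of each loading (covariate-driven variance across the
#' empirical height design plus the summed level variances along that
#' loading) and the noise remainder. For an identified model the shares are
#' reported in decreasing-loading order and sum to 100% minus the noise
#' share.
#'
#' @param model an identified `factor_model`.
#' @param trajectories the data (used for the empirical covariate design).
#' @return List with `shares` (percent per loading), `noise_share`
#'   (percent) and `total_variance`.
#' @export
variance_explained <- function(model, trajectories) {
  dat <- .fa_data(trajectories, model$design, model$reference)
  B <- dat$X %*% model$beta                      # n x q covariate effect
  var_beta <- apply(B, 2L, function(x) mean((x - mean(x))^2))
  lat <- vapply(seq_len(model$q), function(k) {
    sum(vapply(model$Sigma, function(S) S[k, k], numeric(1)))
  }, numeric(1))
  per_loading <- var_beta + lat
  noise <- 30 * sum(model$Lambda)
  total <- sum(per_loading) + noise
  list(shares = 100 * per_loading / total,
       noise_share = 100 * noise / total,
       total_variance = total)
}

#' Likelihood-ratio test of linear height scaling
#'
#' Tests whether the mean-path change with obstacle height is a linear
#' amplification (one-parameter regression in height increase 0 / 7.5 / 15)
#' against the generic two-parameter ANOVA design, by fitting both designs
#' on the same data with the same `q` and convergence tolerances and
#' referring twice the log-likelihood difference to a chi-squared
#' distribution with `q` degrees of freedom. The ANOVA fit is additionally
#' started from the converged regression solution (which it nests) so the
#' statistic is nonnegative up to tolerance.
#'
#' @inheritParams fit_factor_model
#' @param restarts logical; with `TRUE` (default) both designs also get
#'   warm restarts from each other's converged solutions (the ANOVA design
#'   nests the regression optimum exactly; the regression design is
#'   restarted from the least-squares projection of the ANOVA optimum), so
#'   neither model receives more optimization effort than the other. With
#'   `FALSE` only the regression fit and the nested-initialization ANOVA
#'   fit are run, which is cheaper and still guarantees a nonnegative
#'   statistic.
#' @param ... further arguments passed to [fit_factor_model()].
#' @return List with `statistic`, `p_value`, `df`, `loglik_anova`,
#'   `loglik_regression`.
#' @export
lrt_height_design <- function(trajectories, q, max_iter = 500L, tol = 1e-9,
                              restarts = TRUE, ...) {
  fit_r1 <- fit_factor_model(trajectories, q, design = "regression",
                             max_iter = max_iter, tol = tol,
                             identify = FALSE, ...)
  # the ANOVA design nests the regression optimum: mean_h = X_h beta_r with
  # X = 0, 7.5, 15 equals the ANOVA means with beta_a = (7.5 beta_r; 15 beta_r)
  nested_init <- list(beta = rbind(7.5 * fit_r1$beta, 15 * fit_r1$beta),
                      Sigma = fit_r1$Sigma, Lambda = fit_r1$Lambda,
                      W = fit_r1$W)
  fit_a2 <- fit_factor_model(trajectories, q, design = "anova",
                             max_iter = max_iter, tol = tol,
                             init = nested_init, identify = FALSE, ...)
  ll_a <- fit_a2$loglik
  ll_r <- fit_r1$loglik
  if (restarts) {
    fit_a1 <- fit_factor_model(trajectories, q, design = "anova",
                               max_iter = max_iter, tol = tol,
                               identify = FALSE, ...)
    Xa <- .fa_design_levels("anova")
    xr <- .fa_design_levels("regression")
    proj_beta <- solve(crossprod(xr), crossprod(xr, Xa %*% fit_a1$beta))
    proj_init <- list(beta = proj_beta, Sigma = fit_a1$Sigma,
                      Lambda = fit_a1$Lambda, W = fit_a1$W)
    fit_r2 <- fit_factor_model(trajectories, q, design = "regression",
                               max_iter = max_iter, tol = tol,
                               init = proj_init, identify = FALSE, ...)
    ll_a <- max(ll_a, fit_a1$loglik)
    ll_r <- max(ll_r, fit_r2$loglik)
    if (fit_r2$loglik > ll_a) {
      # the projected restart improved the null fit past the ANOVA fits:
      # re-nest once so the alternative is at least as good
      fit_best_r <- if (fit_r2$loglik >= fit_r1$loglik) fit_r2 else fit_r1
      fit_a3 <- fit_factor_model(trajectories, q, design = "anova",
                                 max_iter = max_iter, tol = tol,
                                 init = list(
                                   beta = rbind(7.5 * fit_best_r$beta,
                                                15 * fit_best_r$beta),
                                   Sigma = fit_best_r$Sigma,
                                   Lambda = fit_best_r$Lambda,
                                   W = fit_best_r$W),
                                 identify = FALSE, ...)
      ll_a <- max(ll_a, fit_a3$loglik)
    }
  }
  stat <- 2 * (ll_a - ll_r)
  if (stat < -1e-6 * (abs(ll_a) + 1)) {
    stop("nesting violated: regression log likelihood exceeds ANOVA; ",
         "fits did not converge", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = q, lower.tail = FALSE),
       df = q, loglik_anova = ll_a, loglik_regression = ll_r)
}

#' Prediction ellipsoid of a random-effect level at a path point
#'
#' Marginal 3-D spatial covariance contributed by one random-effect level
#' at one of the 30 path points: \eqn{W_t \Sigma_l W_t^\top}, where
#' \eqn{W_t} is the 3 x q block of loadings for that time point. The
#' coverage ellipsoid is obtained from its eigendecomposition scaled by the
#' chi-squared(3) quantile.
#'
#' @param model an identified `factor_model`.
#' @param level `"participant"`, `"height_reaction"` or `"repetition"`.
#' @param time_index path point, 1..30.
#' @param coverage coverage probability in (0, 1), default 0.95.
#' @return List with `covariance` (3 x 3), `radii` (semi-axis lengths),
#'   `axes` (columns are the principal directions) and `center` (the
#'   reference-path point).
#' @export
level_ellipsoids <- function(model, level = c("participant", "height_reaction",
                                              "repetition"),
                             time_index, coverage = 0.95) {
  level <- match.arg(level)
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must lie strictly between 0 and 1", call. = FALSE)
  }
  time_index <- as.integer(time_index)
  if (time_index < 1L || time_index > 30L) {
    stop("`time_index` must be in 1..30", call. = FALSE)
  }
  l <- match(level, c("participant", "height_reaction", "repetition"))
  rows <- (3L * (time_index - 1L) + 1L):(3L * time_index)
  Wt <- model$W[rows, , drop = FALSE]
  cov3 <- .fa_sym(Wt %*% model$Sigma[[l]] %*% t(Wt))
  ee <- eigen(cov3, symmetric = TRUE)
  scale <- stats::qchisq(coverage, df = 3)
  list(covariance = cov3,
       radii = sqrt(pmax(ee$values, 0) * scale),
       axes = ee$vectors,
       center = model$theta[time_index, ])
}
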