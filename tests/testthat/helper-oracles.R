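# Independent oracle implementations used to validate the package's
# computations. These deliberately use naive dense formulations and
# independent code paths (recursions, quadrature, full-matrix solves).

# --- Cox-de Boor recursion for B-spline basis values -------------------

cox_de_boor <- function(knots, x, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- function(i, p, t) {
    if (p == 0L) {
      # right-closed at the final boundary so t = 1 is covered
      if (knots[i] <= t && t < knots[i + 1L]) return(1)
      if (t == knots[length(knots)] && knots[i] < t &&
          t <= knots[i + 1L]) return(1)
      return(0)
    }
    left <- 0
    if (knots[i + p] > knots[i]) {
      left <- (t - knots[i]) / (knots[i + p] - knots[i]) * B(i, p - 1L, t)
    }
    right <- 0
    if (knots[i + p + 1L] > knots[i + 1L]) {
      right <- (knots[i + p + 1L] - t) / (knots[i + p + 1L] - knots[i + 1L]) *
        B(i + 1L, p - 1L, t)
    }
    left + right
  }
  out <- matrix(0, length(x), n_basis)
  for (k in seq_along(x)) {
    for (i in seq_len(n_basis)) out[k, i] <- B(i, degree, x[k])
  }
  out
}

# --- Bessel K via its integral representation --------------------------

bessel_k_integral <- function(x, nu) {
  vapply(x, function(xx) {
    stats::integrate(function(t) exp(-xx * cosh(t)) * cosh(nu * t),
                     0, 30, rel.tol = 1e-12)$value
  }, numeric(1))
}

# --- dense GLS / ridge-GLS oracles (full m x m weight matrix) ----------

# Builds the full stacked design and block-diagonal I + S and solves the
# normal equations by explicit inversion.
dense_gls_oracle <- function(samples, basis, amplitude, warps = NULL,
                             eta = NULL, c_hat = NULL) {
  n_w <- if (is.null(warps)) 0L else ncol(warps$nu)
  pids <- sort(unique(vapply(samples, function(s) s$participant_id,
                             integer(1))))
  Phis <- list(); Ks <- list(); ys <- list(); pis <- integer(0)
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    keep <- !s$missing_mask
    t <- s$times[keep]
    pi <- match(s$participant_id, pids)
    wt <- if (n_w == 0L) t else
      eval_warp(warps$nu[pi, ], warps$w[k, ], t)
    Phis[[k]] <- bspline_design(basis, pmin(pmax(wt, 0), 1))
    M <- diag(length(t))
    if (amplitude$tau2 > 0) {
      M <- M + outer(t, t, function(a, b)
        matern_cov(abs(a - b), amplitude$mu, amplitude$tau2,
                   amplitude$alpha))
    }
    Ks[[k]] <- M
    ys[[k]] <- s$values[keep]
    pis <- c(pis, pi)
  }
  Phi <- do.call(rbind, Phis)
  y <- unlist(ys)
  m <- length(y)
  Kfull <- matrix(0, m, m)
  off <- 0L
  for (k in seq_along(Ks)) {
    n <- nrow(Ks[[k]])
    Kfull[(off + 1):(off + n), (off + 1):(off + n)] <- Ks[[k]]
    off <- off + n
  }
  Winv <- solve(Kfull)
  if (is.null(eta)) {
    return(drop(solve(t(Phi) %*% Winv %*% Phi) %*% t(Phi) %*% Winv %*% y))
  }
  # ridge-GLS deviations per participant around a given template c_hat
  lens <- vapply(ys, length, integer(1))
  ends <- cumsum(lens); offs <- c(1L, head(ends, -1L) + 1L)
  d <- matrix(0, length(pids), basis$n_basis)
  for (i in seq_along(pids)) {
    rows <- unlist(lapply(which(pis == i), function(k) offs[k]:ends[k]))
    Pi <- Phi[rows, , drop = FALSE]
    Wi <- solve(Kfull[rows, rows])
    ri <- y[rows] - drop(Pi %*% c_hat)
    d[i, ] <- drop(solve(t(Pi) %*% Wi %*% Pi + eta * diag(basis$n_basis)) %*%
                     t(Pi) %*% Wi %*% ri)
  }
  d
}

# --- dense linearized-likelihood oracle (full V formed) ----------------

dense_nll_oracle <- function(samples, linearization, w0, sigma2, amplitude,
                             gamma2) {
  n_w <- ncol(as.matrix(w0))
  C <- if (n_w > 0L) brownian_bridge_cov(warp_anchor_points(n_w), gamma2)
       else matrix(0, 0, 0)
  rs <- list(); Vs <- list()
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    keep <- !s$missing_mask
    t <- s$times[keep]
    n <- length(t)
    S <- matrix(0, n, n)
    if (amplitude$tau2 > 0) {
      S <- outer(t, t, function(a, b)
        matern_cov(abs(a - b), amplitude$mu, amplitude$tau2, amplitude$alpha))
    }
    Zk <- linearization$Z[[k]]
    V <- S + diag(n)
    if (n_w > 0L) V <- V + Zk %*% C %*% t(Zk)
    r <- s$values[keep] - linearization$vartheta[[k]]
    if (n_w > 0L) r <- r + drop(Zk %*% as.matrix(w0)[k, ])
    rs[[k]] <- r; Vs[[k]] <- V
  }
  m <- sum(vapply(rs, length, integer(1)))
  Vfull <- matrix(0, m, m)
  off <- 0L
  for (k in seq_along(Vs)) {
    n <- nrow(Vs[[k]])
    Vfull[(off + 1):(off + n), (off + 1):(off + n)] <- Vs[[k]]
    off <- off + n
  }
  r <- unlist(rs)
  m * log(sigma2) + determinant(Vfull, logarithm = TRUE)$modulus[1] +
    drop(r %*% solve(Vfull) %*% r) / sigma2
}

# --- dense linear mixed model ML oracle (n_w = 0 limit) ----------------

# Exact marginal ML for y = Phi c + x + eps with Matern x, by direct
# optimization of the profile likelihood using dense per-curve matrices.
dense_lmm_oracle <- function(samples, basis, mu,
                             init = c(tau2 = 1, alpha = 5)) {
  prep_t <- lapply(samples, function(s) s$times[!s$missing_mask])
  prep_y <- lapply(samples, function(s) s$values[!s$missing_mask])
  Phis <- lapply(prep_t, function(t) bspline_design(basis, t))
  m <- sum(lengths(prep_y))
  obj <- function(lp) {
    tau2 <- exp(lp[1]); alpha <- exp(lp[2])
    A <- matrix(0, basis$n_basis, basis$n_basis)
    b <- numeric(basis$n_basis)
    Vinvs <- list(); logdet <- 0
    for (k in seq_along(samples)) {
      t <- prep_t[[k]]
      V <- diag(length(t)) + outer(t, t, function(a, bb)
        matern_cov(abs(a - bb), mu, tau2, alpha))
      Vinv <- solve(V)
      logdet <- logdet + determinant(V, logarithm = TRUE)$modulus[1]
      A <- A + t(Phis[[k]]) %*% Vinv %*% Phis[[k]]
      b <- b + t(Phis[[k]]) %*% Vinv %*% prep_y[[k]]
      Vinvs[[k]] <- Vinv
    }
    ch <- solve(A, b)
    quad <- 0
    for (k in seq_along(samples)) {
      r <- prep_y[[k]] - drop(Phis[[k]] %*% ch)
      quad <- quad + drop(r %*% Vinvs[[k]] %*% r)
    }
    m * log(quad / m) + logdet + m
  }
  opt <- stats::optim(log(unname(init)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  tau2 <- exp(opt$par[1]); alpha <- exp(opt$par[2])
  # recover sigma2 at the optimum
  A <- matrix(0, basis$n_basis, basis$n_basis)
  b <- numeric(basis$n_basis)
  quad <- 0
  Vinvs <- list()
  for (k in seq_along(samples)) {
    t <- prep_t[[k]]
    V <- diag(length(t)) + outer(t, t, function(a, bb)
      matern_cov(abs(a - bb), mu, tau2, alpha))
    Vinvs[[k]] <- solve(V)
    A <- A + t(Phis[[k]]) %*% Vinvs[[k]] %*% Phis[[k]]
    b <- b + t(Phis[[k]]) %*% Vinvs[[k]] %*% prep_y[[k]]
  }
  ch <- solve(A, b)
  for (k in seq_along(samples)) {
    r <- prep_y[[k]] - drop(Phis[[k]] %*% ch)
    quad <- quad + drop(r %*% Vinvs[[k]] %*% r)
  }
  list(sigma2 = quad / m, tau2 = tau2, alpha = alpha, value = opt$value,
       c = drop(ch))
}

# --- misc helpers ------------------------------------------------------

principal_angle_deg <- function(A, B) {
  QA <- qr.Q(qr(A)); QB <- qr.Q(qr(B))
  s <- svd(crossprod(QA, QB))$d
  acos(min(1, max(-1, min(s)))) * 180 / pi
}

make_grid_samples <- function(values_list, tgrid, pids, rids,
                              condition = "c1") {
  lapply(seq_along(values_list), function(k) {
    functional_sample(pids[k], rids[k], condition, tgrid, values_list[[k]])
  })
}
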