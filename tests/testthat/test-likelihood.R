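# Toy fixtures shared by the likelihood tests
toy_gls_fixture <- function(seed = 10, n_t = 10L, K = 5L) {
  set.seed(seed)
  basis <- spline_basis(K)
  tgrid <- seq(0, 1, length.out = n_t)
  cc <- rnorm(basis$n_basis)
  samples <- list(
    functional_sample(1, 1, "c", tgrid,
                      drop(bspline_design(basis, tgrid) %*% cc) + rnorm(n_t, sd = 0.3)),
    functional_sample(2, 1, "c", tgrid,
                      drop(bspline_design(basis, tgrid) %*% cc) + rnorm(n_t, sd = 0.3)))
  list(basis = basis, samples = samples, tgrid = tgrid, cc = cc)
}

test_that("template GLS reduces to OLS when S = 0", {
  fx <- toy_gls_fixture()
  amplitude <- list(mu = 1, tau2 = 0, alpha = 1)
  c_hat <- estimate_template(fx$samples, fx$basis, amplitude = amplitude)
  # ordinary least squares on the stacked design
  Phi <- do.call(rbind, lapply(fx$samples, function(s)
    bspline_design(fx$basis, s$times)))
  y <- unlist(lapply(fx$samples, `[[`, "values"))
  expect_equal(c_hat, drop(qr.coef(qr(Phi), y)), tolerance = 1e-10)
})

test_that("template GLS satisfies the weighted normal equations", {
  fx <- toy_gls_fixture()
  amplitude <- list(mu = 1, tau2 = 0.5, alpha = 5)
  c_hat <- estimate_template(fx$samples, fx$basis, amplitude = amplitude)
  resid_score <- numeric(fx$basis$n_basis)
  for (s in fx$samples) {
    Phi <- bspline_design(fx$basis, s$times)
    Km <- diag(length(s$times)) + matern_matrix(s$times, 1, 0.5, 5)
    resid_score <- resid_score +
      drop(t(Phi) %*% solve(Km) %*% (s$values - Phi %*% c_hat))
  }
  expect_lt(max(abs(resid_score)), 1e-8)
})

test_that("template GLS matches the dense direct-solve oracle", {
  fx <- toy_gls_fixture()
  amplitude <- list(mu = 1, tau2 = 0.5, alpha = 5)
  c_hat <- estimate_template(fx$samples, fx$basis, amplitude = amplitude)
  c_oracle <- dense_gls_oracle(fx$samples, fx$basis, amplitude)
  expect_equal(c_hat, c_oracle, tolerance = 1e-10)
})

test_that("deviation updates: infinite penalty shrinks to zero, zero penalty interpolates", {
  fx <- toy_gls_fixture(n_t = 12L)
  amplitude <- list(mu = 1, tau2 = 0, alpha = 1)
  c_hat <- estimate_template(fx$samples, fx$basis, amplitude = amplitude)
  dev <- estimate_deviations(fx$samples, fx$basis, c_hat,
                             amplitude = amplitude, eta = 1e12,
                             center = FALSE)
  expect_lt(max(abs(dev$d)), 1e-6)

  # exact representation: y_i = Phi (c + d*) recovered with eta = 0
  basis <- fx$basis
  tgrid <- fx$tgrid
  d_star <- rbind(seq(-0.5, 0.5, length.out = basis$n_basis),
                  -seq(-0.5, 0.5, length.out = basis$n_basis))
  exact <- lapply(1:2, function(i) {
    functional_sample(i, 1, "c", tgrid,
                      drop(bspline_design(basis, tgrid) %*% (fx$cc + d_star[i, ])))
  })
  dev2 <- estimate_deviations(exact, basis, fx$cc, amplitude = amplitude,
                              eta = 0, center = FALSE)
  expect_equal(dev2$d, d_star, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("deviation ridge-GLS matches the dense oracle and re-centers", {
  fx <- toy_gls_fixture()
  amplitude <- list(mu = 1, tau2 = 0.5, alpha = 5)
  eta <- 0.7
  c_hat <- estimate_template(fx$samples, fx$basis, amplitude = amplitude)
  dev <- estimate_deviations(fx$samples, fx$basis, c_hat,
                             amplitude = amplitude, eta = eta, center = FALSE)
  d_oracle <- dense_gls_oracle(fx$samples, fx$basis, amplitude, eta = eta,
                               c_hat = c_hat)
  expect_equal(dev$d, d_oracle, tolerance = 1e-10, ignore_attr = TRUE)

  centered <- estimate_deviations(fx$samples, fx$basis, c_hat,
                                  amplitude = amplitude, eta = eta)
  expect_equal(colSums(centered$d), rep(0, fx$basis$n_basis),
               tolerance = 1e-12, ignore_attr = TRUE)
  # fitted values preserved by the centering shift
  for (i in 1:2) {
    expect_equal(c_hat + dev$d[i, ], centered$c + centered$d[i, ],
                 tolerance = 1e-12)
  }
})

test_that("warp posterior is zero for exact unwarped data and reduces to the prior for flat templates", {
  set.seed(21)
  basis <- spline_basis(6L)
  tgrid <- seq(0, 1, length.out = 20)
  cc <- rnorm(basis$n_basis)
  amplitude <- list(mu = 1, tau2 = 0.3, alpha = 4)
  y <- drop(bspline_design(basis, tgrid) %*% cc)
  s <- functional_sample(1, 1, "c", tgrid, y)
  val0 <- warp_posterior(list(s), nu_anchors = 0.5, w = matrix(0, 1, 1),
                         c = cc, d_i = rep(0, basis$n_basis), basis = basis,
                         amplitude = amplitude, gamma2 = 0.4)
  expect_equal(val0, 0, tolerance = 1e-16)

  # constant template: residual is invariant to warping, so the posterior
  # equals the Brownian-bridge prior term exactly
  c_flat <- rep(2, basis$n_basis)
  s_flat <- functional_sample(1, 1, "c", tgrid, rep(2, 20))
  w <- matrix(0.07, 1, 1)
  val <- warp_posterior(list(s_flat), 0.5, w, c_flat,
                        rep(0, basis$n_basis), basis, amplitude,
                        gamma2 = 0.4)
  Cm <- brownian_bridge_cov(0.5, 0.4)
  expect_equal(val, drop(w %*% solve(Cm) %*% t(w)), tolerance = 1e-12)

  # inadmissible warp: barrier
  expect_identical(
    warp_posterior(list(s), 0.5, matrix(0.9, 1, 1), cc,
                   rep(0, basis$n_basis), basis, amplitude, 0.4), Inf)
})

test_that("warp posterior matches a brute-force recomputation over a w grid", {
  set.seed(11)
  basis <- spline_basis(6L)
  tgrid <- seq(0, 1, length.out = 15)
  cc <- rnorm(basis$n_basis)
  amplitude <- list(mu = 1, tau2 = 0.3, alpha = 4)
  gamma2 <- 0.4
  y <- drop(bspline_design(basis, eval_warp(0.5, 0.08, tgrid)) %*% cc) +
    rnorm(15, sd = 0.1)
  s <- functional_sample(3, 1, "c", tgrid, y)
  Km <- diag(15) + matern_matrix(tgrid, 1, 0.3, 4)
  Cm <- brownian_bridge_cov(0.5, gamma2)
  for (wv in seq(-0.2, 0.2, by = 0.05)) {
    val <- warp_posterior(list(s), 0.5, matrix(wv, 1, 1), cc,
                          rep(0, basis$n_basis), basis, amplitude, gamma2)
    # independent recomputation from scratch
    wt <- pmin(pmax(stats::approx(c(0, 0.5, 1), c(0, 0.5 + wv, 1),
                                  xout = tgrid)$y, 0), 1)
    r <- y - drop(bspline_design(basis, wt) %*% cc)
    brute <- drop(r %*% solve(Km) %*% r) + wv^2 / Cm[1, 1]
    expect_equal(val, brute, tolerance = 1e-10)
  }
})

test_that("linearization: constant template gives Z = 0, identity point gives the template", {
  basis <- spline_basis(6L)
  tgrid <- seq(0, 1, length.out = 18)
  s <- functional_sample(1, 1, "c", tgrid, rnorm(18))
  warps <- list(nu = matrix(0.5, 1, 1), w = matrix(0, 1, 1))
  lin_flat <- linearize_model(list(s), basis, rep(3, basis$n_basis),
                              matrix(0, 1, basis$n_basis), warps)
  expect_equal(lin_flat$Z[[1]], matrix(0, 18, 1), ignore_attr = TRUE)

  cc <- rnorm(basis$n_basis)
  lin_id <- linearize_model(list(s), basis, cc,
                            matrix(0, 1, basis$n_basis), warps)
  expect_equal(lin_id$vartheta[[1]],
               drop(bspline_design(basis, tgrid) %*% cc))
})

test_that("Z matches numerical directional derivatives of the warped prediction", {
  set.seed(12)
  basis <- spline_basis(8L)
  tgrid <- seq(0, 1, length.out = 25)
  cc <- rnorm(basis$n_basis)
  d <- matrix(rnorm(basis$n_basis, sd = 0.2), 1)
  n_w <- 2L
  nu <- warp_anchor_points(n_w) + c(0.03, -0.02)
  w0 <- c(0.02, 0.01)
  s <- functional_sample(1, 1, "c", tgrid, rnorm(25))
  warps <- list(nu = matrix(nu, 1), w = matrix(w0, 1))
  lin <- linearize_model(list(s), basis, cc, d, warps)
  pred <- function(w) {
    wt <- pmin(pmax(eval_warp(nu, w, tgrid), 0), 1)
    drop(bspline_design(basis, wt) %*% (cc + d[1, ]))
  }
  h <- 1e-6
  for (l in seq_len(n_w)) {
    e <- numeric(n_w); e[l] <- h
    fd <- (pred(w0 + e) - pred(w0 - e)) / (2 * h)
    denom <- max(abs(fd), 1e-3)
    expect_lt(max(abs(lin$Z[[1]][, l] - fd)) / denom, 1e-4)
  }
})

test_that("linearized likelihood: white-noise reduction and curve exchangeability", {
  set.seed(13)
  basis <- spline_basis(6L)
  tgrid <- seq(0, 1, length.out = 15)
  cc <- rnorm(basis$n_basis)
  d <- matrix(0, 2, basis$n_basis)
  samples <- lapply(1:2, function(i)
    functional_sample(i, 1, "c", tgrid, rnorm(15)))
  warps <- list(nu = matrix(rep(0.5, 2), 2), w = matrix(0, 2, 1))
  lin <- linearize_model(samples, basis, cc, d, warps)
  # Z = 0, S = 0, sigma2 = 1: criterion is the plain residual sum of squares
  lin0 <- lin
  lin0$Z <- lapply(lin0$Z, function(Z) Z * 0)
  val <- linearized_nll(samples, lin0, matrix(0, 2, 1), sigma2 = 1,
                        amplitude = list(mu = 1, tau2 = 0, alpha = 1),
                        gamma2 = 0.3)
  rss <- sum(vapply(1:2, function(k)
    sum((samples[[k]]$values - lin$vartheta[[k]])^2), numeric(1)))
  expect_equal(val, rss, tolerance = 1e-10)

  # permutation invariance over curves
  amplitude <- list(mu = 1, tau2 = 0.4, alpha = 5)
  v1 <- linearized_nll(samples, lin, matrix(c(0.01, -0.02), 2, 1), 0.5,
                       amplitude, 0.3)
  lin_perm <- list(vartheta = lin$vartheta[2:1], Z = lin$Z[2:1])
  v2 <- linearized_nll(samples[2:1], lin_perm,
                       matrix(c(-0.02, 0.01), 2, 1), 0.5, amplitude, 0.3)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("linearized likelihood matches the dense-V oracle", {
  set.seed(14)
  basis <- spline_basis(7L)
  tgrid <- seq(0, 1, length.out = 15)
  cc <- rnorm(basis$n_basis)
  d <- matrix(rnorm(2 * basis$n_basis, sd = 0.1), 2)
  samples <- lapply(1:2, function(i)
    functional_sample(i, 1, "c", tgrid, rnorm(15)))
  warps <- list(nu = matrix(rep(0.5, 2), 2),
                w = matrix(c(0.03, -0.01), 2, 1))
  lin <- linearize_model(samples, basis, cc, d, warps)
  amplitude <- list(mu = 1, tau2 = 0.6, alpha = 4)
  val <- linearized_nll(samples, lin, warps$w, sigma2 = 0.2, amplitude,
                        gamma2 = 0.5)
  oracle <- dense_nll_oracle(samples, lin, warps$w, 0.2, amplitude, 0.5)
  expect_equal(val, oracle, tolerance = 1e-8)
})

test_that("eta normalization follows lambda / (1 + tau2)", {
  expect_equal(eta_from_lambda(2, 1), 1)
  expect_equal(eta_from_lambda(0, 17.3), 0)
  expect_equal(eta_from_lambda(3, 0), 3)
  expect_error(eta_from_lambda(-1, 1), "nonnegative")
})

test_that("template and deviation updates never increase the fixed-warp criterion", {
  set.seed(15)
  sim <- simulate_curves(n_participants = 3, n_repetitions = 3,
                         n_timepoints = 25, seed = 16)
  basis <- spline_basis(8L)
  amplitude <- list(mu = 1, tau2 = 0.5, alpha = 5)
  crit <- function(cc, d) {
    total <- 0
    for (s in sim$samples) {
      i <- s$participant_id
      Phi <- bspline_design(basis, s$times)
      Km <- diag(length(s$times)) + matern_matrix(s$times, 1, 0.5, 5)
      r <- s$values - drop(Phi %*% (cc + d[i, ]))
      total <- total + drop(r %*% solve(Km) %*% r)
    }
    total
  }
  cc <- rep(0, basis$n_basis)
  d <- matrix(0, 3, basis$n_basis)
  vals <- numeric(4)
  for (it in 1:4) {
    cc <- estimate_template(sim$samples, basis, amplitude = amplitude)
    dev <- estimate_deviations(sim$samples, basis, cc,
                               amplitude = amplitude, eta = 0)
    cc <- dev$c; d <- dev$d
    vals[it] <- crit(cc, d)
  }
  expect_true(all(diff(vals) <= 1e-8))
})
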