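small_factor_sim <- function(seed = 61, n_p = 5L, n_r = 3L, q = 2L, ...) {
  simulate_trajectories(n_participants = n_p, n_repetitions = n_r, q = q,
                        seed = seed, ...)
}

test_that("ECM log likelihood is nondecreasing at every accepted step", {
  sim <- small_factor_sim()
  fit <- fit_factor_model(sim$trajectories, q = 2, design = "anova")
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_true(fit$converged)
  # plain ECM (no acceleration) agrees on the optimum
  fit_plain <- fit_factor_model(sim$trajectories, q = 2, design = "anova",
                                squarem = FALSE, max_iter = 2000)
  expect_equal(fit$loglik, fit_plain$loglik, tolerance = 1e-5)
})

test_that("identification invariants hold after fitting", {
  sim <- small_factor_sim(seed = 62)
  fit <- fit_factor_model(sim$trajectories, q = 3, design = "anova")
  expect_lt(max(abs(crossprod(fit$W) - diag(3))), 1e-8)
  tot <- Reduce(`+`, fit$Sigma)
  expect_lt(max(abs(tot - diag(diag(tot)))), 1e-8)
  expect_true(all(diff(diag(tot)) <= 1e-10))   # decreasing diagonal
  expect_true(all(fit$Lambda > 0))
})

test_that("identification is idempotent and likelihood-invariant", {
  sim <- small_factor_sim(seed = 63)
  fit <- fit_factor_model(sim$trajectories, q = 2, design = "regression",
                          identify = FALSE)
  ident <- identify_loadings(fit)
  # likelihood unchanged by the identification transform
  ll_before <- factor_model_loglik(fit, sim$trajectories)
  ll_after <- factor_model_loglik(ident, sim$trajectories)
  expect_equal(ll_before, ll_after, tolerance = 1e-8)
  # idempotence
  twice <- identify_loadings(ident)
  expect_lt(max(abs(twice$W - ident$W)), 1e-10)
  expect_lt(max(abs(twice$beta - ident$beta)), 1e-10)
  for (l in 1:3) {
    expect_lt(max(abs(twice$Sigma[[l]] - ident$Sigma[[l]])), 1e-10)
  }
})

test_that("a random rotation is undone by identification", {
  sim <- small_factor_sim(seed = 64)
  fit <- fit_factor_model(sim$trajectories, q = 3, design = "anova")
  set.seed(65)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rotated <- fit
  rotated$W <- fit$W %*% Q
  rotated$beta <- fit$beta %*% Q
  rotated$Sigma <- lapply(fit$Sigma, function(S) t(Q) %*% S %*% Q)
  back <- identify_loadings(rotated)
  expect_equal(back$W, fit$W, tolerance = 1e-6)
  expect_equal(back$beta, fit$beta, tolerance = 1e-6)
})

test_that("noise-free low-rank data are reproduced exactly", {
  q <- 2L
  sim <- simulate_trajectories(n_participants = 4, n_repetitions = 2,
                               q = q, Lambda = rep(1e-30, 3), seed = 66)
  fit <- fit_factor_model(sim$trajectories, q = q, design = "anova",
                          max_iter = 300)
  expect_lt(max(fit$Lambda), 1e-6)
  # residuals of the fitted subspace representation vanish
  dat_theta <- as.vector(t(fit$theta))
  for (s in sim$trajectories[1:5]) {
    y0 <- as.vector(t(s$path)) - dat_theta
    resid <- y0 - drop(fit$W %*% crossprod(fit$W, y0))
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("variance shares sum to 100 percent minus the noise share", {
  sim <- small_factor_sim(seed = 67)
  fit <- fit_factor_model(sim$trajectories, q = 2, design = "anova")
  ve <- variance_explained(fit, sim$trajectories)
  expect_equal(sum(ve$shares) + ve$noise_share, 100, tolerance = 1e-8)
  expect_true(all(ve$shares >= 0))
  # loadings are ordered: shares decrease with the loading index for the
  # latent part; with covariate variance added, totals remain positive
  sim_nless <- simulate_trajectories(n_participants = 4, n_repetitions = 2,
                                     q = 1, Lambda = rep(1e-30, 3),
                                     seed = 68)
  fitq1 <- fit_factor_model(sim_nless$trajectories, q = 1, design = "anova")
  ve1 <- variance_explained(fitq1, sim_nless$trajectories)
  expect_equal(ve1$shares[1] + ve1$noise_share, 100, tolerance = 1e-6)
  expect_gt(ve1$shares[1], 99.9)   # q = 1, essentially no noise
})

test_that("variance shares recover the generating composition", {
  q <- 2L
  Sigma <- list(diag(c(0.8, 0.2)), diag(c(0.7, 0.2)), diag(c(3.5, 0.6)))
  lat_true <- c(5, 1)   # summed level variances per loading
  noise_true <- 30 * 3 * 0.02
  shares_true <- 100 * lat_true / (sum(lat_true) + noise_true)
  errs <- vapply(1:20, function(r) {
    sim <- simulate_trajectories(n_participants = 20, n_repetitions = 6,
                                 q = q, Sigma = Sigma,
                                 beta = matrix(0, 2, q),
                                 Lambda = rep(0.02, 3), seed = 100 + r)
    fit <- fit_factor_model(sim$trajectories, q = q, design = "anova")
    ve <- variance_explained(fit, sim$trajectories)
    max(abs(ve$shares - shares_true))
  }, numeric(1))
  expect_lt(stats::median(errs), 2)   # within 2 percentage points
})

test_that("the height-design LRT behaves under nesting", {
  # a strong nonlinear height effect is detected
  q <- 2L
  beta_nl <- rbind(c(4, 0), c(0.5, 2))  # M and T effects far from linear
  sim <- simulate_trajectories(n_participants = 6, n_repetitions = 3,
                               q = q, beta = beta_nl, design = "anova",
                               Lambda = rep(0.02, 3), seed = 70)
  lrt <- lrt_height_design(sim$trajectories, q = q, max_iter = 300,
                           tol = 1e-8)
  expect_gte(lrt$statistic, 0)
  expect_lt(lrt$p_value, 0.001)
  expect_equal(lrt$df, q)

  # under a regression-truth simulation the statistic is small
  simr <- simulate_trajectories(n_participants = 6, n_repetitions = 3,
                                q = q, design = "regression",
                                Lambda = rep(0.02, 3), seed = 71)
  lrt0 <- lrt_height_design(simr$trajectories, q = q, max_iter = 300,
                            tol = 1e-8)
  expect_gte(lrt0$statistic, -1e-6)
  expect_gt(lrt0$p_value, 0.01)
})

test_that("prediction ellipsoids follow the chi-squared geometry", {
  sim <- small_factor_sim(seed = 72)
  fit <- fit_factor_model(sim$trajectories, q = 2, design = "anova")
  ell <- level_ellipsoids(fit, "participant", time_index = 15)
  Wt <- fit$W[(3 * 14 + 1):(3 * 15), , drop = FALSE]
  expect_equal(ell$covariance, Wt %*% fit$Sigma[[1]] %*% t(Wt),
               tolerance = 1e-10)
  # radii are sqrt(eigenvalue x chi2 quantile)
  ev <- eigen(ell$covariance, symmetric = TRUE)$values
  expect_equal(ell$radii, sqrt(pmax(ev, 0) * qchisq(0.95, 3)),
               tolerance = 1e-10)

  # zero covariance level gives a degenerate point ellipsoid
  degen <- fit
  degen$Sigma[[3]] <- matrix(0, 2, 2)
  e0 <- level_ellipsoids(degen, "repetition", 10)
  expect_equal(e0$radii, c(0, 0, 0))

  # isotropic construction: radii all sqrt of the chi2(3) 0.95 quantile
  iso <- fit
  iso$W <- diag(90)[, 1:3]   # selects coordinates of time point 1
  iso$q <- 3L
  iso$Sigma[[1]] <- diag(3)
  ei <- level_ellipsoids(iso, "participant", 1, coverage = 0.95)
  expect_equal(ei$covariance, diag(3))
  expect_equal(ei$radii, rep(sqrt(qchisq(0.95, 3)), 3), tolerance = 1e-12)
  expect_equal(ei$radii, rep(sqrt(7.814728), 3), tolerance = 1e-6)

  expect_error(level_ellipsoids(fit, "participant", 15, coverage = 1.2),
               "coverage")
  expect_error(level_ellipsoids(fit, "participant", 31), "1..30")
})

test_that("ellipsoid volume is invariant under consistent spatial rotation", {
  sim <- small_factor_sim(seed = 73)
  fit <- fit_factor_model(sim$trajectories, q = 2, design = "anova")
  e1 <- level_ellipsoids(fit, "participant", 12)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- lapply(sim$trajectories, function(s)
    trajectory_sample(s$participant_id, s$repetition_id, s$height_level,
                      s$path %*% t(R), s$distance_cm))
  fit2 <- fit_factor_model(rot, q = 2, design = "anova")
  e2 <- level_ellipsoids(fit2, "participant", 12)
  expect_equal(prod(pmax(e1$radii, 1e-12)), prod(pmax(e2$radii, 1e-12)),
               tolerance = 0.05)
})
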