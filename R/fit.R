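# Alternating maximum-likelihood estimation for the hierarchical warping
# model: inner iterations alternate joint warp estimation/prediction with
# GLS template updates; outer iterations re-estimate the variance parameters
# by minimizing the linearized marginal likelihood.

# Exact piecewise-cubic representation of a spline curve: Taylor
# coefficients about each inter-knot midpoint (the spline is a single cubic
# inside each interval, so this is exact and allows fast Horner evaluation).
.ppoly_from_coef <- function(basis, coef) {
  nseg <- basis$K - 1L
  mids <- (seq_len(nseg) - 0.5) / nseg
  dmat <- vapply(0:3, function(dd) {
    drop(splines::splineDesign(basis$knots, mids, ord = 4L,
                               derivs = rep(dd, nseg)) %*% coef)
  }, numeric(nseg))
  list(nseg = nseg, mids = mids,
       c0 = dmat[, 1L], c1 = dmat[, 2L], c2 = dmat[, 3L] / 2,
       c3 = dmat[, 4L] / 6)
}

.ppoly_eval <- function(pp, u, deriv = FALSE) {
  idx <- pmin(pmax(floor(u * pp$nseg), 0), pp$nseg - 1L) + 1L
  dx <- u - pp$mids[idx]
  if (deriv) {
    (3 * pp$c3[idx] * dx + 2 * pp$c2[idx]) * dx + pp$c1[idx]
  } else {
    ((pp$c3[idx] * dx + pp$c2[idx]) * dx + pp$c1[idx]) * dx + pp$c0[idx]
  }
}

# Internal joint optimizer over (nu_i, {w_ij}) for one participant.
# `pc` holds precomputed per-curve pieces: t, y, H (hat weights of the
# anchors), hR (right-boundary hat weight, so the warp is H (nu+w) + hR),
# chol(I+S). Spline design evaluation is batched across the participant's
# curves.
.optimize_participant_warps <- function(pc, nu0, w0, coef, basis, Cinv,
                                        maxit = 100L, multistart = TRUE) {
  n_w <- length(nu0)
  J <- length(pc)
  pack <- function(nu, w) c(nu, t(w))
  unpack <- function(par) {
    list(nu = par[seq_len(n_w)],
         w = matrix(par[-seq_len(n_w)], nrow = J, byrow = TRUE))
  }
  big <- 1e10
  lens <- vapply(pc, function(cv) length(cv$t), integer(1))
  ends <- cumsum(lens)
  offs <- c(1L, utils::head(ends, -1L) + 1L)
  curve_of <- rep(seq_len(J), lens)
  Hbig <- do.call(rbind, lapply(pc, `[[`, "H"))
  hRbig <- unlist(lapply(pc, `[[`, "hR"), use.names = FALSE)
  ybig <- unlist(lapply(pc, `[[`, "y"), use.names = FALSE)
  Kinvs <- lapply(pc, function(cv) chol2inv(cv$chol))

  warped_all <- function(p) {
    wt <- drop(Hbig %*% p$nu) + rowSums(Hbig * p$w[curve_of, , drop = FALSE]) +
      hRbig
    wt[wt < 0] <- 0
    wt[wt > 1] <- 1
    wt
  }
  valid_all <- function(p) {
    vals <- sweep(p$w, 2L, p$nu, "+")
    all(vals > 0) && all(vals < 1) &&
      (n_w == 1L || all(vals[, -1L, drop = FALSE] >
                          vals[, -n_w, drop = FALSE]))
  }

  pp <- .ppoly_from_coef(basis, coef)

  fn <- function(par) {
    p <- unpack(par)
    if (!valid_all(p)) return(big)
    wt <- warped_all(p)
    rbig <- ybig - .ppoly_eval(pp, wt)
    total <- 0
    for (j in seq_len(J)) {
      r <- rbig[offs[j]:ends[j]]
      total <- total + sum(r * (Kinvs[[j]] %*% r)) +
        sum(p$w[j, ] * (Cinv %*% p$w[j, ]))
    }
    total
  }
  gr <- function(par) {
    p <- unpack(par)
    wt <- warped_all(p)
    deriv <- .ppoly_eval(pp, wt, deriv = TRUE)
    rbig <- ybig - .ppoly_eval(pp, wt)
    gnu <- numeric(n_w)
    gw <- matrix(0, J, n_w)
    for (j in seq_len(J)) {
      sel <- offs[j]:ends[j]
      Kinv_r <- drop(Kinvs[[j]] %*% rbig[sel])
      gcommon <- -2 * drop(crossprod(pc[[j]]$H, Kinv_r * deriv[sel]))
      gnu <- gnu + gcommon
      gw[j, ] <- gcommon + 2 * drop(Cinv %*% p$w[j, ])
    }
    c(gnu, t(gw))
  }

  inits <- list(pack(nu0, w0),
                pack(warp_anchor_points(n_w), matrix(0, J, n_w)))
  if (!multistart || max(abs(inits[[1L]] - inits[[2L]])) < 1e-12) {
    inits <- inits[1L]
  }
  best <- NULL
  for (s in inits) {
    opt <- stats::optim(s, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-9))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  id_val <- fn(pack(warp_anchor_points(n_w), matrix(0, J, n_w)))
  if (best$value > id_val) {
    # no valid descent from identity: fall back with a warning flag
    return(c(unpack(pack(warp_anchor_points(n_w), matrix(0, J, n_w))),
             list(value = id_val, fell_back = TRUE)))
  }
  c(unpack(best$par), list(value = best$value, fell_back = FALSE))
}

#' Estimate and predict the warps of one participant
#'
#' Jointly minimizes the warp posterior ([warp_posterior()]) over the
#' participant's fixed warp anchors `nu` and all repetition anchor
#' deviations `w`, restricted to valid homeomorphisms (inadmissible
#' proposals are rejected by a barrier). A bounded-descent quasi-Newton
#' search (BFGS with analytic gradients) is started both from the supplied
#' values and from the identity warp; if no valid descent from the identity
#' is found, identity warps are returned with a warning flag.
#'
#' @inheritParams warp_posterior
#' @param nu_init,w_init starting values (defaults: identity, zeros).
#' @param maxit maximum quasi-Newton iterations.
#' @return List with `nu`, `w` (matrix), `value` (posterior at the optimum)
#'   and `fell_back` (logical).
#' @export
predict_warps <- function(samples_i, c, d_i, basis, n_w,
                          amplitude = list(mu = 1, tau2 = 0, alpha = 1),
                          gamma2 = 1, nu_init = NULL, w_init = NULL,
                          maxit = 100L) {
  prep <- .prep_curves(samples_i)
  if (n_w == 0L) {
    return(list(nu = numeric(0), w = matrix(0, length(prep$curves), 0L),
                value = NA_real_, fell_back = FALSE))
  }
  chols <- .curve_chols(prep$curves, amplitude$mu, amplitude$tau2,
                        amplitude$alpha)
  pc <- lapply(seq_along(prep$curves), function(k) {
    cv <- prep$curves[[k]]
    list(t = cv$t, y = cv$y, H = warp_design(cv$t, n_w),
         hR = .warp_hatR(cv$t, n_w), chol = chols[[k]])
  })
  Cinv <- solve(brownian_bridge_cov(warp_anchor_points(n_w), gamma2))
  if (is.null(nu_init)) nu_init <- warp_anchor_points(n_w)
  if (is.null(w_init)) w_init <- matrix(0, length(pc), n_w)
  .optimize_participant_warps(pc, nu_init, as.matrix(w_init), c + d_i,
                              basis, Cinv, maxit = maxit)
}

#' Estimate variance parameters from the linearized likelihood
#'
#' Minimizes the linearized marginal likelihood ([linearized_nll()]) over
#' the variance parameters. The noise variance `sigma2` is profiled out in
#' closed form; `tau2`, `alpha` and (for `n_w > 0`) `gamma2` are optimized
#' on the log scale by L-BFGS-B within `[1e-10, 1e6]`. The Matern smoothness
#' `mu` is a hyperparameter fixed by configuration (chosen on a grid, never
#' optimized continuously).
#'
#' @inheritParams linearized_nll
#' @param init named list/vector with starting values `tau2`, `alpha`,
#'   `gamma2`.
#' @param mu fixed Matern smoothness.
#' @param bounds length-2 numeric, parameter bounds (applied on log scale).
#' @return List with `sigma2`, `tau2`, `alpha`, `gamma2`, `value` (the
#'   criterion at the optimum) and `convergence`.
#' @export
estimate_variances <- function(samples, linearization, w0, mu = 1,
                               init = list(tau2 = 1, alpha = 5, gamma2 = 0.1),
                               bounds = c(1e-10, 1e6)) {
  prep <- .prep_curves(samples)
  w0 <- as.matrix(w0)
  n_w <- ncol(w0)
  anchors <- warp_anchor_points(n_w)
  laginfos <- lapply(prep$curves, function(cv) .lag_info(cv$t))
  m <- prep$m

  obj <- function(logpar) {
    tau2 <- exp(logpar[1L])
    alpha <- exp(logpar[2L])
    gamma2 <- if (n_w > 0L) exp(logpar[3L]) else 0
    C <- if (n_w > 0L) brownian_bridge_cov(anchors, gamma2)
         else matrix(0, 0L, 0L)
    parts <- tryCatch(
      .nll_blocks(prep, linearization, w0, C,
                  list(mu = mu, tau2 = tau2, alpha = alpha), laginfos),
      error = function(e) NULL)
    if (is.null(parts) || !is.finite(parts$logdet) || parts$quad <= 0) {
      return(1e10)
    }
    # profile out sigma2: minimizer is quad / m
    m * log(parts$quad / m) + parts$logdet + m
  }

  p0 <- log(c(init$tau2, init$alpha, if (n_w > 0L) init$gamma2))
  opt <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = rep(log(bounds[1L]), length(p0)),
                      upper = rep(log(bounds[2L]), length(p0)),
                      control = list(maxit = 200L, factr = 1e3))
  if (opt$value > obj(p0) + 1e-8) {
    warning("variance optimizer did not improve on the initial value; ",
            "returning last feasible iterate")
  }
  tau2 <- exp(opt$par[1L])
  alpha <- exp(opt$par[2L])
  gamma2 <- if (n_w > 0L) exp(opt$par[3L]) else 0
  C <- if (n_w > 0L) brownian_bridge_cov(anchors, gamma2)
       else matrix(0, 0L, 0L)
  parts <- .nll_blocks(prep, linearization, w0, C,
                       list(mu = mu, tau2 = tau2, alpha = alpha), laginfos)
  list(sigma2 = parts$quad / m, tau2 = tau2, alpha = alpha, gamma2 = gamma2,
       value = opt$value, convergence = opt$convergence)
}

#' Fit the hierarchical warping model
#'
#' Alternating maximum-likelihood estimation: the template and participant
#' deviations are initialized under identity warps; inner iterations
#' alternate joint warp estimation/prediction (minimizing the warp
#' posterior) with GLS template updates, breaking early when the warps no
#' longer change; outer iterations re-estimate the variance parameters by
#' minimizing the linearized (Laplace-type) marginal likelihood at the
#' current warp predictions. With `n_w = 0` the model degrades gracefully to
#' a linear mixed model (no warps; the linearized likelihood is then exact).
#'
#' @param samples list of [functional_sample()] with times in \[0, 1\].
#' @param K number of spline knots for the template basis.
#' @param n_w number of warp anchor points (0 disables warping).
#' @param lambda raw deviation penalty; the effective ridge weight is
#'   re-derived as `eta = lambda / (1 + tau2)` whenever `tau2` is updated.
#' @param mu fixed Matern smoothness (grid hyperparameter).
#' @param i_max,j_max outer/inner iteration caps (default 5 each).
#' @param init starting values for `tau2`, `alpha`, `gamma2`.
#' @param warp_maxit per-participant quasi-Newton iteration cap.
#' @param warp_tol convergence threshold on the maximum absolute change of
#'   any anchor value.
#' @return An object of class `warping_fit`: a list with `c`, `d`,
#'   `sigma2`, `tau2`, `alpha`, `gamma2`, `mu`, `lambda`, `eta`, `nu`
#'   (matrix of participant anchors), `w` (matrix of repetition anchor
#'   predictions), `trace` (linearized criterion per outer iteration),
#'   `converged`, plus the `basis`, `n_w` and participant ids.
#' @export
fit_warping_model <- function(samples, K = 12L, n_w = 2L, lambda = 0,
                              mu = 1, i_max = 5L, j_max = 5L,
                              init = list(tau2 = 1, alpha = 5, gamma2 = 0.1),
                              warp_maxit = 100L, warp_tol = 1e-4) {
  prep <- .prep_curves(samples)
  basis <- spline_basis(K)
  n_w <- as.integer(n_w)
  anchors <- warp_anchor_points(n_w)
  nc <- length(prep$curves)

  tau2 <- init$tau2; alpha <- init$alpha; gamma2 <- init$gamma2
  eta <- eta_from_lambda(lambda, tau2)
  nu <- matrix(rep(anchors, each = prep$np), nrow = prep$np)
  w <- matrix(0, nc, n_w)
  warps <- list(nu = nu, w = w)
  amplitude <- list(mu = mu, tau2 = tau2, alpha = alpha)

  chols <- .curve_chols(prep$curves, mu, tau2, alpha)
  cc <- .gls_template(prep, chols, basis, warps)
  dev <- .gls_deviations(prep, chols, basis, cc, warps, eta)
  cc <- dev$c; d <- dev$d
  sigma2 <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  curve_part <- vapply(prep$curves, function(cv) cv$pi, integer(1))

  hatmats <- if (n_w > 0L) lapply(prep$curves, function(cv) {
    list(H = warp_design(cv$t, n_w), hR = .warp_hatR(cv$t, n_w))
  }) else NULL

  for (i in seq_len(i_max)) {
    if (n_w > 0L) {
      Cinv <- solve(brownian_bridge_cov(anchors, gamma2))
      for (j in seq_len(j_max)) {
        old <- c(warps$nu, warps$w)
        for (p in seq_len(prep$np)) {
          idx <- which(curve_part == p)
          pc <- lapply(idx, function(k) {
            cv <- prep$curves[[k]]
            list(t = cv$t, y = cv$y, H = hatmats[[k]]$H,
                 hR = hatmats[[k]]$hR, chol = chols[[k]])
          })
          res <- .optimize_participant_warps(pc, warps$nu[p, ],
                                             warps$w[idx, , drop = FALSE],
                                             cc + d[p, ], basis, Cinv,
                                             maxit = warp_maxit,
                                             multistart = (j == 1L))
          warps$nu[p, ] <- res$nu
          warps$w[idx, ] <- res$w
        }
        if (max(abs(c(warps$nu, warps$w) - old)) < warp_tol) {
          converged <- TRUE
          break
        }
        cc <- .gls_template(prep, chols, basis, warps)
        dev <- .gls_deviations(prep, chols, basis, cc, warps, eta)
        cc <- dev$c; d <- dev$d
      }
    } else {
      cc <- .gls_template(prep, chols, basis, warps)
      dev <- .gls_deviations(prep, chols, basis, cc, warps, eta)
      cc <- dev$c; d <- dev$d
      converged <- TRUE
    }

    lin <- linearize_model(samples, basis, cc, d, warps)
    vres <- estimate_variances(samples, lin, warps$w, mu = mu,
                               init = list(tau2 = tau2, alpha = alpha,
                                           gamma2 = max(gamma2, 1e-8)))
    sigma2 <- vres$sigma2; tau2 <- vres$tau2; alpha <- vres$alpha
    if (n_w > 0L) gamma2 <- vres$gamma2
    eta <- eta_from_lambda(lambda, tau2)
    amplitude <- list(mu = mu, tau2 = tau2, alpha = alpha)
    chols <- .curve_chols(prep$curves, mu, tau2, alpha)
    trace <- c(trace, vres$value)
    if (!all(is.finite(trace))) {
      stop(sprintf("non-finite linearized criterion at outer iteration %d", i),
           call. = FALSE)
    }
  }

  structure(
    list(c = cc, d = d, sigma2 = sigma2, tau2 = tau2, alpha = alpha,
         gamma2 = gamma2, mu = mu, lambda = lambda, eta = eta,
         nu = warps$nu, w = warps$w, trace = trace, converged = converged,
         basis = basis, n_w = n_w, participant_ids = prep$pids),
    class = "warping_fit"
  )
}

#' @export
print.warping_fit <- function(x, ...) {
  cat(sprintf(
    "<warping_fit> %d participants, K = %d, n_w = %d\n  sigma2 = %.4g, tau2 = %.4g, alpha = %.4g, gamma2 = %.4g\n  converged: %s (criterion %.6g)\n",
    length(x$participant_ids), x$basis$K, x$n_w, x$sigma2, x$tau2, x$alpha,
    x$gamma2, x$converged, utils::tail(x$trace, 1L)))
  invisible(x)
}

#' Serialize / restore a fitted warping model
#'
#' JSON checkpointing of a [fit_warping_model()] result.
#'
#' @param fit a `warping_fit` object.
#' @param path file path.
#' @return `path` (write) or the restored `warping_fit` (read).
#' @export
write_warping_fit <- function(fit, path) {
  out <- unclass(fit)
  out$basis <- list(K = fit$basis$K)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_warping_fit
#' @export
read_warping_fit <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$basis <- spline_basis(x$basis$K)
  np <- length(x$participant_ids)
  fix_mat <- function(m, nr) {
    if (is.matrix(m)) m
    else if (is.null(m) || length(m) == 0L) matrix(numeric(0), nr, 0L)
    else matrix(m, nrow = nr, byrow = TRUE)
  }
  x$d <- fix_mat(x$d, np)
  x$nu <- fix_mat(x$nu, np)
  x$w <- fix_mat(x$w, if (is.matrix(x$w)) nrow(x$w) else length(x$w))
  class(x) <- "warping_fit"
  x
}
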