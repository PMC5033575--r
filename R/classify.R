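# Posterior-distance classification of test repetitions to participants,
# with chronological cross-validation, plus a simple unwarped
# nearest-template baseline for comparison.

#' Classify a test repetition by posterior distance
#'
#' Timing-and-motion-separation classification: for each candidate
#' participant the warp posterior ([warp_posterior()]) is minimized over the
#' test repetition's warp anchors `w` only, with the participant's fixed
#' warp `nu` held at its fitted value (a participant trait learned from
#' training data). The test sample is assigned to the participant with the
#' least posterior distance to the fitted template
#' \eqn{(\theta + \varphi_i)\circ\nu_i}; ties break to the lowest
#' participant id.
#'
#' @param test_sample a [functional_sample()] with times in \[0, 1\].
#' @param fit a fitted [fit_warping_model()] object.
#' @param maxit quasi-Newton iteration cap per candidate.
#' @return The predicted participant id, with the per-participant posterior
#'   distances attached as attribute `"scores"`.
#' @export
classify_participant <- function(test_sample, fit, maxit = 100L) {
  stopifnot(inherits(fit, "warping_fit"))
  np <- length(fit$participant_ids)
  if (np < 1L) stop("fitted model has no participant templates", call. = FALSE)
  amplitude <- list(mu = fit$mu, tau2 = fit$tau2, alpha = fit$alpha)
  n_w <- fit$n_w
  prep <- .prep_curves(list(test_sample))
  cv <- prep$curves[[1L]]
  chol_K <- .curve_chols(list(cv), fit$mu, fit$tau2, fit$alpha)[[1L]]
  scores <- numeric(np)
  if (n_w == 0L) {
    for (i in seq_len(np)) {
      r <- cv$y - drop(bspline_design(fit$basis, cv$t) %*% (fit$c + fit$d[i, ]))
      scores[i] <- .quad_solve(chol_K, r)
    }
  } else {
    Cinv <- solve(brownian_bridge_cov(warp_anchor_points(n_w), fit$gamma2))
    pc <- list(list(t = cv$t, y = cv$y, H = warp_design(cv$t, n_w),
                    chol = chol_K))
    for (i in seq_len(np)) {
      nu_i <- fit$nu[i, ]
      coef <- fit$c + fit$d[i, ]
      # minimize over w only: profile the repetition warp per candidate
      fn <- function(wv) {
        if (!is_valid_homeomorphism(nu_i, wv)) return(1e10)
        wt <- .warped_times(nu_i, wv, cv$t)
        r <- cv$y - drop(bspline_design(fit$basis, wt) %*% coef)
        .quad_solve(chol_K, r) + drop(wv %*% Cinv %*% wv)
      }
      gr <- function(wv) {
        wt <- .warped_times(nu_i, wv, cv$t)
        Phi <- bspline_design(fit$basis, wt)
        r <- cv$y - drop(Phi %*% coef)
        Kinv_r <- backsolve(chol_K, backsolve(chol_K, r, transpose = TRUE))
        deriv <- drop(bspline_design(fit$basis, wt, deriv = 1L) %*% coef)
        -2 * drop(crossprod(pc[[1L]]$H, Kinv_r * deriv)) +
          2 * drop(Cinv %*% wv)
      }
      opt <- stats::optim(rep(0, n_w), fn, gr, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-10))
      scores[i] <- min(opt$value, fn(rep(0, n_w)))
    }
  }
  out <- fit$participant_ids[which.min(scores)]
  attr(out, "scores") <- stats::setNames(scores, fit$participant_ids)
  out
}

#' Unwarped nearest-template baseline classifier
#'
#' A deliberately simple baseline: per-participant templates are pointwise
#' mean curves of the training samples (no time warping), and a test sample
#' is assigned to the participant whose template has the least L2 distance
#' at the test sample's observation times.
#'
#' @param test_sample a [functional_sample()].
#' @param train_samples list of training [functional_sample()] objects.
#' @return The predicted participant id, with distances attached as
#'   attribute `"scores"`.
#' @export
classify_nearest_template <- function(test_sample, train_samples) {
  pids <- sort(unique(vapply(train_samples, function(s) s$participant_id,
                             integer(1))))
  tt <- test_sample$times[!test_sample$missing_mask]
  ty <- test_sample$values[!test_sample$missing_mask]
  scores <- vapply(pids, function(p) {
    curves <- Filter(function(s) s$participant_id == p, train_samples)
    interped <- vapply(curves, function(s) {
      keep <- !s$missing_mask
      stats::approx(s$times[keep], s$values[keep], xout = tt, rule = 2)$y
    }, numeric(length(tt)))
    template <- rowMeans(as.matrix(interped))
    sum((ty - template)^2)
  }, numeric(1))
  out <- pids[which.min(scores)]
  attr(out, "scores") <- stats::setNames(scores, pids)
  out
}

#' Chronological cross-validation folds
#'
#' Splits `n_repetitions` repetition indices into `n_folds` chronological
#' folds: fold 1 tests the earliest repetitions, fold 2 the next block, and
#' so on (e.g. with 10 repetitions and 5 folds, fold 1 tests repetitions
#' 1-2, fold 2 tests 3-4, ...).
#'
#' @param n_repetitions total number of repetitions per participant.
#' @param n_folds number of folds; must divide `n_repetitions`.
#' @return A list of length `n_folds`; each element has `train` and `test`
#'   integer vectors partitioning `1:n_repetitions`.
#' @export
chronological_cv_folds <- function(n_repetitions, n_folds) {
  n_repetitions <- as.integer(n_repetitions)
  n_folds <- as.integer(n_folds)
  if (n_folds < 1L || n_repetitions < 1L || n_repetitions %% n_folds != 0L) {
    stop("`n_folds` must divide `n_repetitions`", call. = FALSE)
  }
  size <- n_repetitions %/% n_folds
  lapply(seq_len(n_folds), function(f) {
    test <- ((f - 1L) * size + 1L):(f * size)
    list(train = setdiff(seq_len(n_repetitions), test), test = test)
  })
}

#' Chronological cross-validated classification accuracy
#'
#' Runs the full classification pipeline under chronological
#' cross-validation: for each fold the warping model is fitted to the
#' training repetitions and every test repetition is classified with
#' [classify_participant()]. Optionally also scores the unwarped
#' nearest-template baseline on the same folds.
#'
#' @param samples list of [functional_sample()] (one condition), with
#'   repetition ids `1..n` for every participant.
#' @param n_folds number of chronological folds.
#' @param baseline logical; also evaluate [classify_nearest_template()].
#' @param ... arguments passed to [fit_warping_model()].
#' @return List with `accuracy`, per-fold accuracies, and (if requested)
#'   `baseline_accuracy`.
#' @export
classification_cv <- function(samples, n_folds = 5L, baseline = FALSE, ...) {
  reps <- sort(unique(vapply(samples, function(s) s$repetition_id, integer(1))))
  folds <- chronological_cv_folds(length(reps), n_folds)
  fold_acc <- numeric(length(folds))
  fold_acc_base <- numeric(length(folds))
  for (f in seq_along(folds)) {
    train_reps <- reps[folds[[f]]$train]
    test_reps <- reps[folds[[f]]$test]
    train <- Filter(function(s) s$repetition_id %in% train_reps, samples)
    test <- Filter(function(s) s$repetition_id %in% test_reps, samples)
    fit <- fit_warping_model(train, ...)
    pred <- vapply(test, function(s) as.integer(classify_participant(s, fit)),
                   integer(1))
    truth <- vapply(test, function(s) s$participant_id, integer(1))
    fold_acc[f] <- mean(pred == truth)
    if (baseline) {
      pred_b <- vapply(test, function(s)
        as.integer(classify_nearest_template(s, train)), integer(1))
      fold_acc_base[f] <- mean(pred_b == truth)
    }
  }
  out <- list(accuracy = mean(fold_acc), fold_accuracy = fold_acc)
  if (baseline) {
    out$baseline_accuracy <- mean(fold_acc_base)
    out$baseline_fold_accuracy <- fold_acc_base
  }
  out
}
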