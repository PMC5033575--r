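#' Acceleration profile from a raw position track
#'
#' Derives the scalar acceleration profile of a movement from raw 3-D marker
#' positions: speed is the central finite difference of the positions (the
#' Euclidean norm of the velocity estimate at the interior time points), and
#' acceleration is the finite difference of that speed magnitude. Central
#' differences are used in the interior; at the two ends of the speed grid a
#' first-order one-sided difference is used, so the output has `T - 2` points
#' located at the interior time stamps.
#'
#' @param track a [raw_track()] object with at least 3 time points.
#' @param participant_id,repetition_id,condition_id labels attached to the
#'   resulting sample.
#' @return A [functional_sample()] with times `timestamps[2:(T-1)]` (seconds)
#'   and the acceleration values.
#' @export
compute_acceleration <- function(track, participant_id = 0L,
                                 repetition_id = 0L, condition_id = "raw") {
  stopifnot(inherits(track, "raw_track"))
  ts <- track$timestamps
  p <- track$positions
  n <- length(ts)
  if (n < 3L) stop("need at least 3 time points to differentiate", call. = FALSE)
  idx <- 2:(n - 1)
  # central-difference velocity at interior points, then its magnitude
  vel <- (p[idx + 1L, , drop = FALSE] - p[idx - 1L, , drop = FALSE]) /
    (ts[idx + 1L] - ts[idx - 1L])
  speed <- sqrt(rowSums(vel^2))
  st <- ts[idx]
  m <- length(speed)
  acc <- numeric(m)
  if (m >= 3L) {
    ii <- 2:(m - 1)
    acc[ii] <- (speed[ii + 1L] - speed[ii - 1L]) / (st[ii + 1L] - st[ii - 1L])
  }
  acc[1L] <- (speed[2L] - speed[1L]) / (st[2L] - st[1L])
  acc[m] <- (speed[m] - speed[m - 1L]) / (st[m] - st[m - 1L])
  functional_sample(participant_id, repetition_id, condition_id,
                    times = st, values = acc)
}

#' Rescale a sample to percentual time
#'
#' Maps a sample to percentual time: movement onset becomes time 0 and offset
#' becomes time 1 (0% and 100% of movement duration); observations outside
#' the detected movement interval are dropped. Onset/offset are detected by a
#' threshold rule: the first/last time the absolute signal exceeds a fraction
#' of its peak absolute value. Exact threshold criteria are a preprocessing
#' choice; the default fraction is 0.05.
#'
#' @param sample a [functional_sample()].
#' @param onset_rule list with `type` either `"first_sample"` (use the full
#'   recorded span) or `"threshold"`, and for the latter `frac`, the fraction
#'   of the peak absolute value (default `0.05`).
#' @return A [functional_sample()] with times in \[0, 1\].
#' @export
to_percentual_time <- function(sample,
                               onset_rule = list(type = "threshold", frac = 0.05)) {
  stopifnot(inherits(sample, "functional_sample"))
  type <- match.arg(onset_rule$type, c("threshold", "first_sample"))
  times <- sample$times
  if (type == "first_sample") {
    onset <- times[1L]
    offset <- times[length(times)]
  } else {
    frac <- if (is.null(onset_rule$frac)) 0.05 else onset_rule$frac
    v <- abs(sample$values)
    v[sample$missing_mask] <- NA_real_
    peak <- max(v, na.rm = TRUE)
    above <- which(!is.na(v) & v > frac * peak)
    if (peak <= 0 || length(above) < 2L) {
      stop("movement onset not detectable under the threshold rule",
           call. = FALSE)
    }
    onset <- times[min(above)]
    offset <- times[max(above)]
  }
  if (offset <= onset) stop("degenerate movement interval", call. = FALSE)
  keep <- times >= onset & times <= offset
  functional_sample(sample$participant_id, sample$repetition_id,
                    sample$condition_id,
                    times = (times[keep] - onset) / (offset - onset),
                    values = sample$values[keep],
                    missing_mask = sample$missing_mask[keep])
}

#' Rescale a dataset to unit value span and unit time span
#'
#' Applies a single affine rescaling, shared across all samples (and hence
#' across all experimental conditions), such that the global span of observed
#' values has length 1 and the global time span is mapped to \[0, 1\]. The
#' returned scale record allows exact inversion.
#'
#' @param samples list of [functional_sample()] objects.
#' @return A list with `samples` (rescaled) and `record` (a scale record
#'   with `value_min`, `value_span`, `time_min`, `time_span`).
#' @seealso [invert_rescale()], [write_scale_record()]
#' @export
rescale_curves <- function(samples) {
  stopifnot(length(samples) > 0L)
  vals <- unlist(lapply(samples, function(s) s$values[!s$missing_mask]))
  if (length(vals) == 0L) stop("no unmasked values", call. = FALSE)
  times <- unlist(lapply(samples, function(s) s$times))
  value_min <- min(vals)
  value_span <- max(vals) - value_min
  time_min <- min(times)
  time_span <- max(times) - time_min
  if (value_span <= 0) stop("degenerate data: zero value span", call. = FALSE)
  if (time_span <= 0) stop("degenerate data: zero time span", call. = FALSE)
  record <- list(value_min = value_min, value_span = value_span,
                 time_min = time_min, time_span = time_span)
  rescaled <- lapply(samples, function(s) {
    functional_sample(s$participant_id, s$repetition_id, s$condition_id,
                      times = (s$times - time_min) / time_span,
                      values = (s$values - value_min) / value_span,
                      missing_mask = s$missing_mask)
  })
  list(samples = rescaled, record = record)
}

#' Invert a dataset rescaling
#'
#' @param samples list of rescaled [functional_sample()] objects.
#' @param record scale record from [rescale_curves()].
#' @return The samples on the original scale.
#' @export
invert_rescale <- function(samples, record) {
  lapply(samples, function(s) {
    functional_sample(s$participant_id, s$repetition_id, s$condition_id,
                      times = s$times * record$time_span + record$time_min,
                      values = s$values * record$value_span + record$value_min,
                      missing_mask = s$missing_mask)
  })
}

#' Resample a 3-D track to 30 aligned path points
#'
#' Temporally aligns and resamples a raw track: track time is normalized to
#' \[0, 1\], transported to warped time through the supplied warp, each
#' coordinate is smoothed by a least-squares cubic B-spline with 10
#' equidistant knots in warped time, and the smooth is evaluated at 30
#' equidistant warped-time points. The result is the 30 x 3 aligned path
#' representation used by the factor model.
#'
#' @param track a [raw_track()].
#' @param warp function mapping normalized track time in \[0, 1\] to warped
#'   time in \[0, 1\] (a valid homeomorphism); defaults to the identity. See
#'   [eval_warp()] for the model's warp family.
#' @param participant_id,repetition_id,height_level,distance_cm labels for
#'   the resulting [trajectory_sample()].
#' @return A [trajectory_sample()].
#' @export
resample_path <- function(track, warp = identity, participant_id = 0L,
                          repetition_id = 0L, height_level = 1L,
                          distance_cm = NA_real_) {
  stopifnot(inherits(track, "raw_track"))
  ts <- track$timestamps
  u <- (ts - ts[1L]) / (ts[length(ts)] - ts[1L])
  wu <- warp(u)
  if (any(!is.finite(wu)) || any(wu < -1e-10) || any(wu > 1 + 1e-10) ||
      any(diff(wu) <= 0)) {
    stop("`warp` must be an increasing map of [0,1] onto [0,1]", call. = FALSE)
  }
  wu <- pmin(pmax(wu, 0), 1)
  basis <- spline_basis(10L)
  X <- bspline_design(basis, wu)
  if (nrow(X) < ncol(X) || qr(X)$rank < ncol(X)) {
    stop("track too short for a 10-knot cubic spline fit", call. = FALSE)
  }
  grid <- seq(0, 1, length.out = 30L)
  Xg <- bspline_design(basis, grid)
  coefs <- qr.coef(qr(X), track$positions)
  trajectory_sample(participant_id, repetition_id, height_level,
                    path = Xg %*% coefs, distance_cm = distance_cm)
}
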