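#' Functional sample
#'
#' Container for one repetition's observed signal \eqn{y_{ij}(t_k)}: a single
#' functional observation belonging to a participant, repetition and
#' experimental condition. Values may be missing (e.g. when motion-capture
#' markers are occluded); missingness is carried in `missing_mask` so the
#' observation grid is preserved.
#'
#' @param participant_id integer participant label.
#' @param repetition_id integer repetition (trial) label.
#' @param condition_id character condition label.
#' @param times numeric vector of strictly increasing observation times.
#'   For model fitting times are expected on \[0, 1\] (see
#'   [to_percentual_time()] and [rescale_curves()]); the container itself only
#'   requires strict monotonicity so raw recordings can be held too.
#' @param values numeric vector of observed values, same length as `times`.
#'   Entries flagged by `missing_mask` may be `NA`.
#' @param missing_mask logical vector, `TRUE` where the value is missing.
#'
#' @return An object of class `functional_sample`.
#' @export
functional_sample <- function(participant_id, repetition_id, condition_id,
                              times, values,
                              missing_mask = is.na(values)) {
  participant_id <- as.integer(participant_id)
  repetition_id <- as.integer(repetition_id)
  condition_id <- as.character(condition_id)
  times <- as.numeric(times)
  values <- as.numeric(values)
  missing_mask <- as.logical(missing_mask)
  if (length(times) != length(values) || length(times) != length(missing_mask)) {
    stop("`times`, `values` and `missing_mask` must have identical lengths",
         call. = FALSE)
  }
  if (length(times) > 0L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values[!missing_mask]))) {
    stop("unmasked `values` must be finite", call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, repetition_id = repetition_id,
         condition_id = condition_id, times = times, values = values,
         missing_mask = missing_mask),
    class = "functional_sample"
  )
}

#' @export
print.functional_sample <- function(x, ...) {
  cat(sprintf(
    "<functional_sample> participant %d, repetition %d, condition '%s': %d points (%d missing)\n",
    x$participant_id, x$repetition_id, x$condition_id,
    length(x$times), sum(x$missing_mask)))
  invisible(x)
}

#' Raw 3-D position track
#'
#' A raw motion-capture track: positions of a single marker in Cartesian
#' coordinates sampled at a (nominally) fixed rate.
#'
#' @param positions numeric T x 3 matrix of x, y, z positions (cm).
#' @param sample_rate_hz sampling rate in Hz (e.g. 110).
#' @param timestamps optional numeric vector of time stamps in seconds;
#'   defaults to `(0:(T-1)) / sample_rate_hz`. Must be strictly increasing and
#'   approximately uniform at `1 / sample_rate_hz`.
#'
#' @return An object of class `raw_track`.
#' @export
raw_track <- function(positions, sample_rate_hz, timestamps = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("`positions` must have 3 columns", call. = FALSE)
  if (!all(is.finite(positions))) stop("`positions` must be finite", call. = FALSE)
  sample_rate_hz <- as.numeric(sample_rate_hz)
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a positive number", call. = FALSE)
  }
  n <- nrow(positions)
  if (is.null(timestamps)) {
    timestamps <- (seq_len(n) - 1) / sample_rate_hz
  }
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != n) {
    stop("`timestamps` must match the number of position rows", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(timestamps)
    if (any(dt <= 0)) stop("`timestamps` must be strictly increasing", call. = FALSE)
    if (any(abs(dt - 1 / sample_rate_hz) > 0.25 / sample_rate_hz)) {
      stop("`timestamps` must be approximately uniform at 1/sample_rate_hz",
           call. = FALSE)
    }
  }
  structure(
    list(sample_rate_hz = sample_rate_hz, positions = positions,
         timestamps = timestamps),
    class = "raw_track"
  )
}

#' @export
print.raw_track <- function(x, ...) {
  cat(sprintf("<raw_track> %d samples at %g Hz (%.2f s)\n",
              nrow(x$positions), x$sample_rate_hz,
              diff(range(x$timestamps))))
  invisible(x)
}

#' Aligned spatial trajectory sample
#'
#' One repetition's temporally aligned movement path, represented by 30
#' sample points (equidistant in warped time) in three spatial dimensions,
#' together with its obstacle-height condition.
#'
#' @param participant_id integer participant label.
#' @param repetition_id integer repetition label.
#' @param height_level obstacle height level, integer in `{1, 2, 3}`
#'   (small, medium, tall).
#' @param path numeric 30 x 3 matrix of spatial coordinates.
#' @param distance_cm obstacle distance covariate in cm (metadata only).
#'
#' @return An object of class `trajectory_sample`.
#' @export
trajectory_sample <- function(participant_id, repetition_id, height_level,
                              path, distance_cm = NA_real_) {
  path <- as.matrix(path)
  if (nrow(path) != 30L || ncol(path) != 3L) {
    stop("`path` must be a 30 x 3 matrix", call. = FALSE)
  }
  if (!all(is.finite(path))) stop("`path` must be finite", call. = FALSE)
  height_level <- as.integer(height_level)
  if (!height_level %in% 1:3) {
    stop("`height_level` must be 1, 2 or 3", call. = FALSE)
  }
  structure(
    list(participant_id = as.integer(participant_id),
         repetition_id = as.integer(repetition_id),
         height_level = height_level,
         distance_cm = as.numeric(distance_cm),
         path = path),
    class = "trajectory_sample"
  )
}

#' @export
print.trajectory_sample <- function(x, ...) {
  cat(sprintf("<trajectory_sample> participant %d, repetition %d, height level %d\n",
              x$participant_id, x$repetition_id, x$height_level))
  invisible(x)
}
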