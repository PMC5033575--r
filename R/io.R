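#' Read functional samples from a long-format table
#'
#' Reads a collection of [functional_sample()] objects from a long-format CSV
#' or JSON file with columns/fields `participant`, `repetition`, `condition`,
#' `time`, `value`. Each distinct (participant, repetition, condition) triple
#' becomes one sample; rows with an empty/absent value become masked entries.
#'
#' @param path path to the file.
#' @param format `"csv"` (comma-separated, header row, empty field = missing)
#'   or `"json"`.
#' @return A list of `functional_sample` objects.
#' @seealso [write_functional_samples()]
#' @export
read_functional_samples <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(value = "numeric")),
    json = as.data.frame(jsonlite::fromJSON(path))
  )
  required <- c("participant", "repetition", "condition", "time", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[c("participant", "repetition", "condition", "time")])) {
    stop("duplicated (participant, repetition, condition, time) rows",
         call. = FALSE)
  }
  keys <- interaction(df$participant, df$repetition, df$condition,
                      drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, keys), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    if (any(diff(d$time) <= 0)) {
      stop("non-monotone times within sample (participant ", d$participant[1],
           ", repetition ", d$repetition[1], ")", call. = FALSE)
    }
    functional_sample(d$participant[1], d$repetition[1], d$condition[1],
                      times = d$time, values = d$value)
  })
  names(out) <- NULL
  out
}

#' Write functional samples to a long-format table
#'
#' @param samples list of [functional_sample()] objects.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_functional_samples <- function(samples, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(participant = s$participant_id, repetition = s$repetition_id,
               condition = s$condition_id, time = s$times,
               value = ifelse(s$missing_mask, NA_real_, s$values))
  }))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a raw 3-D track from CSV
#'
#' Expects columns `t`, `x`, `y`, `z` (time in seconds, positions in cm).
#'
#' @param path path to the CSV file.
#' @param sample_rate_hz sampling rate; if `NULL`, inferred from the median
#'   time step.
#' @return A [raw_track()] object.
#' @export
read_raw_track <- function(path, sample_rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t", "x", "y", "z")
  if (!all(required %in% names(df))) {
    stop("raw track CSV must have columns t, x, y, z", call. = FALSE)
  }
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1 / stats::median(diff(df$t))
  }
  raw_track(cbind(df$x, df$y, df$z), sample_rate_hz, timestamps = df$t)
}

#' Write a raw 3-D track to CSV
#' @param track a [raw_track()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raw_track <- function(track, path) {
  df <- data.frame(t = track$timestamps, x = track$positions[, 1],
                   y = track$positions[, 2], z = track$positions[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read aligned trajectory samples from CSV
#'
#' Long format with columns `participant`, `repetition`, `height`,
#' `time_index` (1..30), `x`, `y`, `z`, and optionally `distance_cm`.
#'
#' @param path path to the CSV file.
#' @return A list of [trajectory_sample()] objects.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "repetition", "height", "time_index", "x", "y", "z")
  if (!all(required %in% names(df))) {
    stop("trajectory CSV must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  keys <- interaction(df$participant, df$repetition, df$height,
                      drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, keys), function(d) {
    d <- d[order(d$time_index), , drop = FALSE]
    if (!identical(as.integer(d$time_index), 1:30)) {
      stop("each trajectory must have time_index 1..30", call. = FALSE)
    }
    trajectory_sample(d$participant[1], d$repetition[1], d$height[1],
                      path = cbind(d$x, d$y, d$z),
                      distance_cm = if ("distance_cm" %in% names(d))
                        d$distance_cm[1] else NA_real_)
  })
  names(out) <- NULL
  out
}

#' Write aligned trajectory samples to CSV
#' @param trajectories list of [trajectory_sample()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- do.call(rbind, lapply(trajectories, function(s) {
    data.frame(participant = s$participant_id, repetition = s$repetition_id,
               height = s$height_level, time_index = 1:30,
               x = s$path[, 1], y = s$path[, 2], z = s$path[, 3],
               distance_cm = s$distance_cm)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a value-and-time scale record
#'
#' Serializes the scale record returned by [rescale_curves()] as JSON so a
#' rescaling can be inverted later.
#'
#' @param record scale record (list with `value_min`, `value_span`,
#'   `time_min`, `time_span`).
#' @param path file path.
#' @return `path` (write) or the record (read).
#' @export
write_scale_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_record
#' @export
read_scale_record <- function(path) {
  jsonlite::fromJSON(path)
}
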