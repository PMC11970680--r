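#' Epoch activity-count series
#'
#' An `epoch_series` is a regular one-minute grid of non-negative integer
#' activity counts for one participant-recording. Epoch `i` (1-based) covers
#' the half-open interval `[start_time + (i-1) min, start_time + i min)`.
#'
#' @param participant_id Single string identifying the participant.
#' @param start_time `POSIXct` start of the first epoch; must fall on a whole
#'   minute.
#' @param counts Integer vector of per-epoch activity counts, all `>= 0`,
#'   length `>= 1`.
#' @param wear Optional logical vector of the same length; `FALSE` marks
#'   epochs the device was not worn. Defaults to all-worn.
#'
#' @return An object of class `epoch_series`: a list with elements
#'   `participant_id`, `start_time`, `counts` and `wear`.
#' @export
epoch_series <- function(participant_id, start_time, counts, wear = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  start_time <- as.POSIXct(start_time, tz = "UTC")
  if (length(start_time) != 1L || is.na(start_time)) {
    stop("`start_time` must be a single non-missing timestamp", call. = FALSE)
  }
  if (as.numeric(start_time) %% 60 != 0) {
    stop("`start_time` must be aligned to a whole minute", call. = FALSE)
  }
  if (length(counts) < 1L) {
    stop("`counts` must have length >= 1", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be non-negative integers with no missing values",
         call. = FALSE)
  }
  counts <- as.integer(counts)
  if (is.null(wear)) wear <- rep(TRUE, length(counts))
  if (length(wear) != length(counts) || anyNA(wear)) {
    stop("`wear` must be a complete logical vector matching `counts`",
         call. = FALSE)
  }
  structure(
    list(
      participant_id = participant_id,
      start_time = start_time,
      counts = counts,
      wear = as.logical(wear)
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> participant %s: %d one-minute epochs from %s UTC (%.1f%% worn)\n",
    x$participant_id, length(x$counts),
    format(x$start_time, "%Y-%m-%d %H:%M"), 100 * mean(x$wear)
  ))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch start times of a series
#'
#' @param x An `epoch_series` or `sleep_wake_series`.
#' @return `POSIXct` vector of each epoch's start time.
#' @export
epoch_times <- function(x) {
  x$start_time + 60 * (seq_along(x$counts %||% x$asleep) - 1)
}

#' Map a timestamp to its epoch index
#'
#' Inverse of [epoch_times()]: a time `t` belongs to the epoch whose half-open
#' minute interval contains it.
#'
#' @param x An `epoch_series`.
#' @param time `POSIXct` vector.
#' @return Integer epoch indices; times outside the series span give `NA`.
#' @export
epoch_index <- function(x, time) {
  time <- as.POSIXct(time, tz = "UTC")
  idx <- floor(as.numeric(difftime(time, x$start_time, units = "mins"))) + 1L
  n <- length(x$counts)
  idx[idx < 1L | idx > n] <- NA_integer_
  as.integer(idx)
}

#' @export
as.data.frame.epoch_series <- function(x, ...) {
  as.data.frame(tibble::tibble(
    participant_id = x$participant_id,
    timestamp = epoch_times(x),
    counts = x$counts,
    wear = x$wear
  ))
}

#' Per-epoch sleep/wake series
#'
#' Binary sleep/wake classification aligned one-to-one with a source
#' [epoch_series()].
#'
#' @param participant_id Single string.
#' @param start_time `POSIXct`, minute-aligned.
#' @param asleep Logical vector; `TRUE` = sleep, `FALSE` = wake.
#' @return An object of class `sleep_wake_series`.
#' @export
sleep_wake_series <- function(participant_id, start_time, asleep) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            is.logical(asleep), length(asleep) >= 1L, !anyNA(asleep))
  start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(participant_id = participant_id, start_time = start_time,
         asleep = asleep),
    class = "sleep_wake_series"
  )
}

#' @export
print.sleep_wake_series <- function(x, ...) {
  cat(sprintf(
    "<sleep_wake_series> participant %s: %d epochs, %.1f%% scored asleep\n",
    x$participant_id, length(x$asleep), 100 * mean(x$asleep)
  ))
  invisible(x)
}

#' @export
length.sleep_wake_series <- function(x) length(x$asleep)

# internal: check that a sleep/wake series is aligned to an epoch series
check_aligned <- function(sw, epochs) {
  if (!inherits(sw, "sleep_wake_series") || !inherits(epochs, "epoch_series")) {
    stop("expected a `sleep_wake_series` and an `epoch_series`", call. = FALSE)
  }
  if (length(sw$asleep) != length(epochs$counts) ||
      !identical(as.numeric(sw$start_time), as.numeric(epochs$start_time))) {
    stop("sleep/wake series is not aligned to the epoch series", call. = FALSE)
  }
  invisible(TRUE)
}

# internal: empty sleep-period table with the canonical columns
empty_periods <- function() {
  tibble::tibble(
    participant_id = character(), onset = integer(), end = integer(),
    duration_min = integer(), source = character()
  )
}
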