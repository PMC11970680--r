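#' Epoch CSV dialect configuration
#'
#' Column names and parsing behaviour for [read_epoch_csv()]. The default
#' dialect expects ISO-8601 minute-resolution timestamps.
#'
#' @param timestamp,counts,wear,participant_id Column names in the file.
#'   `wear` and `participant_id` are optional columns; set to `NULL` to
#'   ignore them even if present.
#' @param tz Time zone applied to parsed timestamps (default `"UTC"`).
#' @param fill_gaps If `TRUE`, missing minutes inside the grid are zero-filled
#'   and marked non-wear; if `FALSE` (default) a gap is an error.
#' @return A list of class `epoch_csv_config`.
#' @export
epoch_csv_config <- function(timestamp = "timestamp", counts = "counts",
                             wear = "wear", participant_id = "participant_id",
                             tz = "UTC", fill_gaps = FALSE) {
  structure(
    list(timestamp = timestamp, counts = counts, wear = wear,
         participant_id = participant_id, tz = tz,
         fill_gaps = isTRUE(fill_gaps)),
    class = "epoch_csv_config"
  )
}

#' Read per-minute epoch counts from CSV
#'
#' Reads a one-minute epoch activity-count file and validates it onto a
#' contiguous minute grid. Files may hold a single recording (no participant
#' column, supply `participant_id`) or be in long format with a participant
#' column, in which case a named list of series is returned.
#'
#' @param path Path to the CSV file.
#' @param config An [epoch_csv_config()].
#' @param participant_id Identifier to use when the file has no participant
#'   column (defaults to the file name without extension).
#' @return An [epoch_series()], or a named list of them for long-format files.
#' @export
read_epoch_csv <- function(path, config = epoch_csv_config(),
                           participant_id = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(config$timestamp, config$counts)) {
    if (!col %in% names(raw)) {
      stop(sprintf("column `%s` not found in %s", col, path), call. = FALSE)
    }
  }
  has_pid <- !is.null(config$participant_id) &&
    config$participant_id %in% names(raw)
  if (has_pid) {
    split_raw <- split(raw, raw[[config$participant_id]])
    out <- lapply(names(split_raw), function(pid) {
      parse_epoch_frame(split_raw[[pid]], config, pid)
    })
    names(out) <- names(split_raw)
    if (length(out) == 1L) out[[1L]] else out
  } else {
    if (is.null(participant_id)) {
      participant_id <- tools::file_path_sans_ext(basename(path))
    }
    parse_epoch_frame(raw, config, participant_id)
  }
}

parse_epoch_frame <- function(df, config, participant_id) {
  ts <- df[[config$timestamp]]
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(ts, tz = config$tz,
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  }
  attr(ts, "tzone") <- "UTC"
  if (anyNA(ts)) stop("unparseable timestamps in epoch file", call. = FALSE)
  if (any(as.numeric(ts) %% 60 != 0)) {
    stop("epoch timestamps must fall on whole minutes", call. = FALSE)
  }
  steps <- diff(as.numeric(ts))
  if (any(steps <= 0)) {
    stop("epoch timestamps must be strictly increasing", call. = FALSE)
  }
  counts <- df[[config$counts]]
  if (any(counts < 0, na.rm = TRUE)) {
    stop("negative activity counts are invalid", call. = FALSE)
  }
  wear <- if (!is.null(config$wear) && config$wear %in% names(df)) {
    as.logical(df[[config$wear]])
  } else {
    rep(TRUE, nrow(df))
  }
  if (any(steps > 60)) {
    if (!config$fill_gaps) {
      stop("gap in the minute grid; set `fill_gaps = TRUE` to zero-fill",
           call. = FALSE)
    }
    full <- seq(ts[1], ts[length(ts)], by = 60)
    pos <- match(as.numeric(ts), as.numeric(full))
    filled_counts <- integer(length(full))
    filled_wear <- rep(FALSE, length(full))   # filled minutes = non-wear
    filled_counts[pos] <- as.integer(counts)
    filled_wear[pos] <- wear
    counts <- filled_counts
    wear <- filled_wear
    ts <- full
  }
  epoch_series(participant_id, ts[1], counts, wear)
}

#' Write an epoch series to CSV
#'
#' Inverse of [read_epoch_csv()] for a single recording; a write-then-read
#' round trip reproduces the counts and grid exactly.
#'
#' @param x An [epoch_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(x, path) {
  stopifnot(inherits(x, "epoch_series"))
  df <- tibble::tibble(
    participant_id = x$participant_id,
    timestamp = format(epoch_times(x), "%Y-%m-%dT%H:%M:%S"),
    counts = x$counts,
    wear = as.integer(x$wear)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# round to the nearest whole minute, ties (exactly 30 s) rounding down
round_to_minute <- function(t) {
  secs <- as.numeric(t)
  m <- floor(secs / 60)
  rem <- secs - m * 60
  as.POSIXct((m + (rem > 30)) * 60, tz = "UTC")
}

#' Read a self-report sleep log
#'
#' One row per night with in-bed and out-of-bed datetimes. Timestamps are
#' rounded to the nearest whole minute (ties round down) so the log lives on
#' the epoch grid; an entry covers the half-open interval
#' `[in_bed, out_bed)`.
#'
#' @param path CSV with columns `participant_id`, `in_bed`, `out_bed`
#'   (ISO-8601 datetimes).
#' @param tz Time zone for parsing (default `"UTC"`).
#' @return A tibble sorted by participant and in-bed time.
#' @export
read_sleep_log <- function(path, tz = "UTC") {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("participant_id", "in_bed", "out_bed")) {
    if (!col %in% names(raw)) {
      stop(sprintf("sleep log is missing column `%s`", col), call. = FALSE)
    }
  }
  parse_dt <- function(v) {
    if (inherits(v, "POSIXct")) {
      attr(v, "tzone") <- "UTC"
      return(v)
    }
    out <- as.POSIXct(v, tz = tz,
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    attr(out, "tzone") <- "UTC"
    out
  }
  log <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    in_bed = round_to_minute(parse_dt(raw$in_bed)),
    out_bed = round_to_minute(parse_dt(raw$out_bed))
  )
  validate_sleep_log(log)
}

#' Validate a sleep-log tibble
#'
#' @param log Tibble with `participant_id`, `in_bed`, `out_bed` (`POSIXct`).
#' @return The log, minute-aligned and sorted, or an error.
#' @export
validate_sleep_log <- function(log) {
  if (anyNA(log$in_bed) || anyNA(log$out_bed)) {
    stop("unparseable datetimes in sleep log", call. = FALSE)
  }
  if (any(log$out_bed <= log$in_bed)) {
    stop("sleep-log entries must have out_bed > in_bed", call. = FALSE)
  }
  log <- dplyr::arrange(log, .data$participant_id, .data$in_bed)
  overlap <- log |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      bad = any(dplyr::lead(.data$in_bed) < .data$out_bed, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    stop("overlapping sleep-log entries for participant(s): ",
         paste(overlap$participant_id[overlap$bad], collapse = ", "),
         call. = FALSE)
  }
  log
}

#' Night-sufficiency eligibility check
#'
#' A participant's recording is eligible when at least `min_nights` logged
#' nights satisfy both conditions: a sleep-log entry exists and the device
#' was worn for at least `wear_fraction` of the logged in-bed window. Nights
#' need not be consecutive.
#'
#' @param epochs An [epoch_series()].
#' @param log Sleep-log tibble for the same participant.
#' @param min_nights Minimum eligible nights (default 5).
#' @param wear_fraction Minimum worn fraction of the logged window
#'   (default 0.8).
#' @return A list with `participant_id`, `n_logged`, `n_eligible_nights`,
#'   `eligible`, and a per-night tibble `nights`.
#' @export
check_night_sufficiency <- function(epochs, log, min_nights = 5,
                                    wear_fraction = 0.8) {
  stopifnot(inherits(epochs, "epoch_series"), min_nights >= 1)
  log <- log[log$participant_id == epochs$participant_id, , drop = FALSE]
  n <- length(epochs)
  nights <- purrr::pmap_dfr(
    list(log$in_bed, log$out_bed),
    function(in_bed, out_bed) {
      i0 <- epoch_index(epochs, in_bed)
      i1 <- epoch_index(epochs, out_bed - 1)   # last covered minute
      in_span <- !is.na(i0) && !is.na(i1)
      worn <- if (in_span) mean(epochs$wear[i0:i1]) else 0
      tibble::tibble(in_bed = in_bed, out_bed = out_bed, in_span = in_span,
                     worn_fraction = worn,
                     eligible = in_span && worn >= wear_fraction)
    }
  )
  n_ok <- if (nrow(nights)) sum(nights$eligible) else 0L
  list(
    participant_id = epochs$participant_id,
    n_logged = nrow(log),
    n_eligible_nights = n_ok,
    eligible = n_ok >= min_nights,
    nights = nights
  )
}
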