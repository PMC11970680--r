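#' Per-period sleep measures
#'
#' Computes the ten standard actigraphy sleep measures for one sleep period:
#' \describe{
#'   \item{latency}{Wake epochs between the period start and its first sleep
#'     epoch (structurally 0 for Tudor-Locke periods).}
#'   \item{efficiency}{`100 * TST / TIB` (percent).}
#'   \item{tib}{Total minutes in bed: the period duration.}
#'   \item{tst}{Total sleep time: sleep-classified minutes in the period.}
#'   \item{waso}{Wake after sleep onset: wake minutes after the first sleep
#'     epoch.}
#'   \item{n_awakenings}{Maximal wake runs after the first sleep epoch (a
#'     single epoch counts as a run).}
#'   \item{avg_awakening_len}{`waso / n_awakenings`; 0 when there are no
#'     awakenings.}
#'   \item{movement_index}{Percent of period epochs with activity
#'     count >= 1.}
#'   \item{fragmentation_index}{Percent of maximal sleep runs lasting exactly
#'     one epoch, among all sleep runs (bout-ratio form). A definition based
#'     on total sleep time instead of the bout count can be selected with
#'     `fi_denominator = "tst"` for sensitivity checks.}
#'   \item{sleep_fragmentation_index}{`movement_index +
#'     fragmentation_index`.}
#' }
#' The identity `tib = latency + tst + waso` holds exactly. Auxiliary counts
#' (`n_active_epochs`, `n_sleep_runs`, `n_sleep_runs_len1`) are returned to
#' support pooled daily aggregation.
#'
#' @param period One row of a period tibble (see [detect_sleep_periods()]).
#' @param sw Aligned [sleep_wake_series()].
#' @param epochs Aligned [epoch_series()].
#' @param fi_denominator `"bouts"` (default) or `"tst"`.
#' @return A one-row tibble of measures.
#' @export
compute_measures <- function(period, sw, epochs, fi_denominator = "bouts") {
  check_aligned(sw, epochs)
  fi_denominator <- match.arg(fi_denominator, c("bouts", "tst"))
  onset <- period$onset[1]
  end <- period$end[1]
  if (is.na(onset) || is.na(end) || end < onset ||
      onset < 1L || end > length(sw$asleep)) {
    stop("period is empty or outside the series span", call. = FALSE)
  }
  asleep <- sw$asleep[onset:end]
  counts <- epochs$counts[onset:end]
  tib <- length(asleep)
  first_sleep <- match(TRUE, asleep)
  if (is.na(first_sleep)) {
    latency <- tib
    tst <- 0L
    waso <- 0L
    n_awake <- 0L
    runs1 <- 0L
    nruns <- 0L
  } else {
    latency <- first_sleep - 1L
    after <- asleep[first_sleep:tib]
    tst <- sum(after)
    waso <- sum(!after)
    r <- rle(after)
    n_awake <- sum(!r$values)
    sleep_runs <- r$lengths[r$values]
    nruns <- length(sleep_runs)
    runs1 <- sum(sleep_runs == 1L)
  }
  n_active <- sum(counts >= 1L)
  mi <- 100 * n_active / tib
  fi <- if (fi_denominator == "bouts") {
    if (nruns > 0L) 100 * runs1 / nruns else 0
  } else {
    if (tst > 0L) 100 * runs1 / tst else 0
  }
  tibble::tibble(
    participant_id = period$participant_id[1],
    onset = onset, end = end, source = period$source[1],
    latency = as.integer(latency),
    efficiency = if (tib > 0) 100 * tst / tib else 0,
    tib = as.integer(tib),
    tst = as.integer(tst),
    waso = as.integer(waso),
    n_awakenings = as.integer(n_awake),
    avg_awakening_len = if (n_awake > 0) waso / n_awake else 0,
    movement_index = mi,
    fragmentation_index = fi,
    sleep_fragmentation_index = mi + fi,
    n_active_epochs = as.integer(n_active),
    n_sleep_runs = as.integer(nruns),
    n_sleep_runs_len1 = as.integer(runs1)
  )
}

#' Measures for every period of a recording
#'
#' @param periods Period tibble.
#' @inheritParams compute_measures
#' @return A tibble with one measure row per period, plus the assigned
#'   calendar day (see [assign_day()]).
#' @export
compute_all_measures <- function(periods, sw, epochs,
                                 fi_denominator = "bouts") {
  if (nrow(periods) == 0L) {
    return(tibble::tibble(
      participant_id = character(), onset = integer(), end = integer(),
      source = character(), latency = integer(), efficiency = double(),
      tib = integer(), tst = integer(), waso = integer(),
      n_awakenings = integer(), avg_awakening_len = double(),
      movement_index = double(), fragmentation_index = double(),
      sleep_fragmentation_index = double(), n_active_epochs = integer(),
      n_sleep_runs = integer(), n_sleep_runs_len1 = integer(),
      day = as.Date(character())
    ))
  }
  res <- purrr::map_dfr(seq_len(nrow(periods)), function(i) {
    compute_measures(periods[i, , drop = FALSE], sw, epochs, fi_denominator)
  })
  res$day <- assign_day(periods, epochs)
  res
}

#' Calendar day of a sleep period
#'
#' A period is assigned to the day it ends: the calendar date containing its
#' final epoch's start (so a period whose last epoch is `[23:59, 00:00)`
#' still belongs to the earlier day).
#'
#' @param periods Period tibble.
#' @param epochs The [epoch_series()] the indices refer to.
#' @return A `Date` vector, one per period.
#' @export
assign_day <- function(periods, epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  last_start <- epochs$start_time + 60 * (periods$end - 1L)
  as.Date(last_start, tz = "UTC")
}

#' Aggregate period measures by calendar day
#'
#' Additive measures (latency, TIB, TST, WASO, awakenings) are summed across
#' a day's periods. Ratio measures are pooled, not averaged: daily efficiency
#' is `100 * sum(TST) / sum(TIB)`, average awakening length is
#' `sum(WASO) / sum(awakenings)`, the movement index pools active epochs over
#' pooled TIB, the fragmentation index pools one-epoch sleep runs over pooled
#' sleep runs, and the daily sleep fragmentation index is the sum of the two
#' pooled indices.
#'
#' @param period_measures Output of [compute_all_measures()] for one
#'   participant and method.
#' @return A tibble with one row per (participant, day).
#' @export
aggregate_daily <- function(period_measures) {
  if (nrow(period_measures) == 0L) {
    return(tibble::tibble(
      participant_id = character(), day = as.Date(character()),
      n_periods = integer(), latency = integer(), efficiency = double(),
      tib = integer(), tst = integer(), waso = integer(),
      n_awakenings = integer(), avg_awakening_len = double(),
      movement_index = double(), fragmentation_index = double(),
      sleep_fragmentation_index = double()
    ))
  }
  if (anyDuplicated(period_measures[, c("participant_id", "onset", "end")])) {
    stop("duplicate period for the same interval", call. = FALSE)
  }
  period_measures |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(
      n_periods = dplyr::n(),
      latency = sum(.data$latency),
      tib = sum(.data$tib),
      tst = sum(.data$tst),
      waso = sum(.data$waso),
      n_awakenings = sum(.data$n_awakenings),
      avg_awakening_len = if (sum(.data$n_awakenings) > 0) {
        sum(.data$waso) / sum(.data$n_awakenings)
      } else 0,
      movement_index = 100 * sum(.data$n_active_epochs) / sum(.data$tib),
      fragmentation_index = if (sum(.data$n_sleep_runs) > 0) {
        100 * sum(.data$n_sleep_runs_len1) / sum(.data$n_sleep_runs)
      } else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      efficiency = 100 * .data$tst / .data$tib,
      sleep_fragmentation_index =
        .data$movement_index + .data$fragmentation_index
    ) |>
    dplyr::select(
      "participant_id", "day", "n_periods", "latency", "efficiency", "tib",
      "tst", "waso", "n_awakenings", "avg_awakening_len", "movement_index",
      "fragmentation_index", "sleep_fragmentation_index"
    )
}

# measure columns shared by period-level and daily tables
measure_names <- function() {
  c("latency", "efficiency", "tib", "tst", "waso", "n_awakenings",
    "avg_awakening_len", "movement_index", "fragmentation_index",
    "sleep_fragmentation_index")
}
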