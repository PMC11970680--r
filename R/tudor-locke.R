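#' Tudor-Locke detection parameters
#'
#' The five tuning parameters of the Tudor-Locke sleep-period detector.
#'
#' @param bedtime_def Minimum consecutive sleep epochs that open a period
#'   (default 5).
#' @param waketime_def Minimum consecutive wake epochs that terminate a
#'   period (default 10).
#' @param min_period_len Minimum accepted period duration in minutes
#'   (default 160).
#' @param min_nonzero_epochs Minimum epochs with activity count >= 1 a period
#'   must contain (default 0); guards against scoring non-wear as sleep.
#' @param max_period_len Periods must be strictly shorter than this many
#'   minutes (default 1440, i.e. under 24 h).
#' @return A list of class `tl_params`.
#' @export
tl_params <- function(bedtime_def = 5, waketime_def = 10,
                      min_period_len = 160, min_nonzero_epochs = 0,
                      max_period_len = 1440) {
  stopifnot(bedtime_def >= 1, waketime_def >= 1,
            min_period_len >= 0, min_nonzero_epochs >= 0,
            min_period_len <= max_period_len)
  structure(
    list(bedtime_def = as.integer(bedtime_def),
         waketime_def = as.integer(waketime_def),
         min_period_len = as.integer(min_period_len),
         min_nonzero_epochs = as.integer(min_nonzero_epochs),
         max_period_len = as.integer(max_period_len)),
    class = "tl_params"
  )
}

#' Default Tudor-Locke parameters
#' @return [tl_params()] with the software defaults (5, 10, 160, 0, 1440).
#' @export
tl_default <- function() tl_params()

#' Tudor-Locke parameters optimized for adults with chronic pain
#'
#' A preset raising the wake-time definition to 25 epochs and the minimum
#' non-zero epochs to 5, the combination that maximizes sleep-log agreement
#' in restless cohorts.
#'
#' @return [tl_params()] with (5, 25, 160, 5, 1440).
#' @export
tl_chronic_pain <- function() {
  tl_params(bedtime_def = 5, waketime_def = 25, min_period_len = 160,
            min_nonzero_epochs = 5, max_period_len = 1440)
}

# Enumerate candidate sleep periods. Candidates depend only on bedtime_def
# and waketime_def: rejection by the length/non-zero filters never moves the
# scan position, so filtering is applied afterwards (see detect_sleep_periods).
tl_candidates <- function(asleep, bedtime_def, waketime_def) {
  n <- length(asleep)
  if (n == 0L) return(cbind(onset = integer(), end = integer()))
  r <- rle(asleep)
  r_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  r_end <- r_start + r$lengths - 1L
  onsets <- integer(0)
  ends <- integer(0)
  pos <- 1L
  i <- 1L
  n_runs <- length(r$lengths)
  while (i <= n_runs) {
    # bedtime: first run of >= bedtime_def consecutive sleep epochs at/after pos
    onset <- NA_integer_
    while (i <= n_runs) {
      if (r$values[i] && r_end[i] >= pos) {
        from <- max(r_start[i], pos)
        if (r_end[i] - from + 1L >= bedtime_def) {
          onset <- from
          break
        }
      }
      i <- i + 1L
    }
    if (is.na(onset)) break
    # terminator: first wake run of >= waketime_def epochs after the onset run
    j <- i + 1L
    term <- NA_integer_
    while (j <= n_runs) {
      if (!r$values[j] && r$lengths[j] >= waketime_def) {
        term <- j
        break
      }
      j <- j + 1L
    }
    if (!is.na(term)) {
      end <- r_start[term] - 1L     # epoch before the wake run; always sleep
      onsets <- c(onsets, onset)
      ends <- c(ends, end)
      pos <- r_end[term] + 1L       # resume after the terminating wake run
      i <- term + 1L
    } else {
      # series ended mid-period: close at the last sleep epoch
      last_sleep <- max(r_end[r$values & r_end >= onset], onset)
      onsets <- c(onsets, onset)
      ends <- c(ends, last_sleep)
      break
    }
  }
  cbind(onset = onsets, end = ends)
}

# internal filter shared by detect_sleep_periods and the grid search
tl_filter_candidates <- function(cand, nz_cum, params) {
  if (nrow(cand) == 0L) return(cand)
  dur <- cand[, "end"] - cand[, "onset"] + 1L
  nz <- nz_cum[cand[, "end"] + 1L] - nz_cum[cand[, "onset"]]
  keep <- dur >= params$min_period_len & dur < params$max_period_len &
    nz >= params$min_nonzero_epochs
  cand[keep, , drop = FALSE]
}

#' Detect sleep periods (Tudor-Locke)
#'
#' Stage two of the pipeline: scans a sleep/wake series left to right. A
#' period opens at the first epoch of a run of at least `bedtime_def`
#' consecutive sleep epochs and ends at the last sleep epoch before the first
#' run of at least `waketime_def` consecutive wake epochs (trailing wake is
#' trimmed; a series ending mid-period is closed at its last sleep epoch).
#' Candidates are kept only if their duration lies in
#' `[min_period_len, max_period_len)` and they contain at least
#' `min_nonzero_epochs` epochs with activity count >= 1; rejected candidates
#' do not block later periods. Every detected period therefore starts and
#' ends on a sleep epoch, which forces sleep-onset latency to zero.
#'
#' @param sw A [sleep_wake_series()].
#' @param epochs The aligned [epoch_series()] (counts drive the non-zero
#'   filter).
#' @param params [tl_params()].
#' @return A tibble of periods with columns `participant_id`, `onset`, `end`
#'   (1-based inclusive epoch indices), `duration_min` and `source = "TL"`.
#' @export
detect_sleep_periods <- function(sw, epochs, params = tl_params()) {
  check_aligned(sw, epochs)
  stopifnot(inherits(params, "tl_params"))
  cand <- tl_candidates(sw$asleep, params$bedtime_def, params$waketime_def)
  nz_cum <- c(0L, cumsum(epochs$counts >= 1L))
  kept <- tl_filter_candidates(cand, nz_cum, params)
  if (nrow(kept) == 0L) return(empty_periods())
  tibble::tibble(
    participant_id = sw$participant_id,
    onset = as.integer(kept[, "onset"]),
    end = as.integer(kept[, "end"]),
    duration_min = as.integer(kept[, "end"] - kept[, "onset"] + 1L),
    source = "TL"
  )
}

#' Sleep periods from a sleep log
#'
#' Converts log entries into periods on the epoch grid, one per entry,
#' covering `[in_bed, out_bed)`. No Tudor-Locke filters apply to log-defined
#' periods.
#'
#' @param log Sleep-log tibble (see [read_sleep_log()]); only rows matching
#'   the series' participant are used.
#' @param epochs An [epoch_series()].
#' @return A period tibble with `source = "LOG"`.
#' @export
periods_from_log <- function(log, epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  log <- log[log$participant_id == epochs$participant_id, , drop = FALSE]
  if (nrow(log) == 0L) return(empty_periods())
  onset <- epoch_index(epochs, log$in_bed)
  end <- epoch_index(epochs, log$out_bed - 1)  # half-open: last covered minute
  if (anyNA(onset) || anyNA(end)) {
    stop("sleep-log entry falls outside the epoch series span", call. = FALSE)
  }
  tibble::tibble(
    participant_id = epochs$participant_id,
    onset = onset,
    end = end,
    duration_min = end - onset + 1L,
    source = "LOG"
  )
}
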