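#' Synthetic actigraphy cohort specification
#'
#' Parameters of the seeded generator. Defaults emulate a small cohort of
#' restless adult sleepers wearing a wrist device for a week: one sleep
#' window per night, long mid-sleep awakening bouts (pain-flare-like), and
#' frequent brief movement during sleep, with self-report logs offset from
#' the true windows by recall noise.
#'
#' Activity counts are drawn from synthetic convenience distributions chosen
#' so the default Cole-Kripke configuration separates the states cleanly:
#' daytime/awakening epochs from a zero-inflated negative binomial with a
#' high mean, sleeping epochs zero except for movement epochs
#' (`Bernoulli(movement_prob)`) whose counts are `1 + Poisson(move_count_mean)`.
#'
#' @param n_participants Cohort size (default 16).
#' @param nights_per_participant Nights per participant (default 7; must be
#'   >= 5 so cohorts pass the night-sufficiency rule).
#' @param mean_bedtime_hour Mean clock hour of bedtime (default 22.5).
#' @param mean_tib Mean true time in bed, minutes (default 538).
#' @param bedtime_jitter_sd,tib_jitter_sd Night-to-night SDs, minutes.
#' @param awakening_rate Mean awakening bouts per night (Poisson).
#' @param awakening_len_range Min/max bout length, minutes (uniform).
#' @param movement_prob Probability a sleeping epoch shows movement
#'   (count >= 1).
#' @param move_count_mean Poisson mean of movement-epoch counts above 1.
#' @param wake_count_mean,wake_count_size Negative-binomial mean/size of
#'   waking counts.
#' @param wake_zero_prob Zero-inflation of waking counts.
#' @param recall_sd SD of Gaussian recall noise on each log boundary,
#'   minutes.
#' @param nonwear_prob Per-day probability of a daytime non-wear block.
#' @param nonwear_len Length of a non-wear block, minutes.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 16, nights_per_participant = 7,
                        mean_bedtime_hour = 22.5, mean_tib = 538,
                        bedtime_jitter_sd = 30, tib_jitter_sd = 45,
                        awakening_rate = 3, awakening_len_range = c(12, 20),
                        movement_prob = 0.12, move_count_mean = 3,
                        wake_count_mean = 250, wake_count_size = 1.2,
                        wake_zero_prob = 0.1, recall_sd = 15,
                        nonwear_prob = 0, nonwear_len = 120) {
  stopifnot(n_participants >= 1, nights_per_participant >= 5,
            mean_tib > 0, bedtime_jitter_sd >= 0, tib_jitter_sd >= 0,
            awakening_rate >= 0, length(awakening_len_range) == 2,
            awakening_len_range[1] <= awakening_len_range[2],
            awakening_len_range[1] >= 1,
            movement_prob >= 0, movement_prob <= 1,
            recall_sd >= 0, nonwear_prob >= 0, nonwear_prob <= 1)
  if (awakening_rate * awakening_len_range[2] >= 0.5 * mean_tib) {
    stop("infeasible spec: expected awakening time exceeds half the sleep ",
         "window", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         nights_per_participant = as.integer(nights_per_participant),
         mean_bedtime_hour = mean_bedtime_hour, mean_tib = mean_tib,
         bedtime_jitter_sd = bedtime_jitter_sd,
         tib_jitter_sd = tib_jitter_sd,
         awakening_rate = awakening_rate,
         awakening_len_range = awakening_len_range,
         movement_prob = movement_prob, move_count_mean = move_count_mean,
         wake_count_mean = wake_count_mean,
         wake_count_size = wake_count_size,
         wake_zero_prob = wake_zero_prob, recall_sd = recall_sd,
         nonwear_prob = nonwear_prob, nonwear_len = as.integer(nonwear_len)),
    class = "cohort_spec"
  )
}

#' Chronic-pain cohort preset
#'
#' The generator's restless-cohort study conditions: 16 participants, 7
#' nights each, ~538 minutes mean time in bed, an elevated awakening rate
#' with 12-20 minute bouts, and frequent within-sleep movement.
#'
#' @return A [cohort_spec()].
#' @export
chronic_pain_preset <- function() {
  cohort_spec(
    n_participants = 16, nights_per_participant = 7,
    mean_bedtime_hour = 22.5, mean_tib = 538,
    bedtime_jitter_sd = 30, tib_jitter_sd = 45,
    awakening_rate = 3, awakening_len_range = c(12, 20),
    movement_prob = 0.12, move_count_mean = 3,
    recall_sd = 15, nonwear_prob = 0
  )
}

# waking-count draw: zero-inflated negative binomial
draw_wake_counts <- function(n, spec) {
  x <- stats::rnbinom(n, mu = spec$wake_count_mean, size = spec$wake_count_size)
  zero <- stats::runif(n) < spec$wake_zero_prob
  x[zero] <- 0L
  as.integer(x)
}

#' Generate a synthetic actigraphy cohort
#'
#' Deterministically (given `seed`) simulates per-minute activity-count
#' series, self-report sleep logs, and the underlying ground truth for a
#' cohort. Each participant's recording starts at noon and spans
#' `nights_per_participant + 1` days. Per night: a true sleep window is drawn
#' around the mean bedtime/time-in-bed; awakening bouts are placed uniformly
#' inside it without overlap; daytime and bout epochs draw waking counts,
#' sleeping epochs are zero except for movement epochs; the log entry is the
#' true window perturbed by recall noise and rounded to minutes.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (required; generation is a pure function of
#'   `(spec, seed)`).
#' @return A list with one element per participant, each a list:
#'   `epochs` ([epoch_series()]), `log` (sleep-log tibble) and `truth`
#'   (tibble of true per-night windows plus an `awakenings` list-column of
#'   epoch-interval matrices).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"), is.numeric(seed))
  set.seed(as.integer(seed))
  origin <- as.POSIXct("2023-03-01 12:00:00", tz = "UTC")
  n_days <- spec$nights_per_participant + 1L
  n_min <- n_days * 1440L
  bed_offset0 <- round((spec$mean_bedtime_hour - 12) * 60)  # minutes past noon

  lapply(seq_len(spec$n_participants), function(p) {
    pid <- sprintf("P%02d", p)
    counts <- draw_wake_counts(n_min, spec)
    wear <- rep(TRUE, n_min)
    truth <- vector("list", spec$nights_per_participant)

    for (j in seq_len(spec$nights_per_participant)) {
      bed_min <- (j - 1L) * 1440L + bed_offset0 +
        round(stats::rnorm(1, 0, spec$bedtime_jitter_sd))
      tib <- round(stats::rnorm(1, spec$mean_tib, spec$tib_jitter_sd))
      tib <- max(240L, min(840L, tib))
      bed_min <- max(0L, min(n_min - tib - 1L, bed_min))
      wake_min <- bed_min + tib
      idx <- (bed_min + 1L):wake_min          # 1-based epoch indices, half-open

      # baseline sleep: zeros with sporadic movement
      sl <- integer(tib)
      mv <- stats::runif(tib) < spec$movement_prob
      sl[mv] <- 1L + stats::rpois(sum(mv), spec$move_count_mean)
      counts[idx] <- sl

      # awakening bouts, uniform start, non-overlapping, away from the edges
      k <- stats::rpois(1, spec$awakening_rate)
      k <- min(k, max(0L, floor((tib - 60) /
                                  (spec$awakening_len_range[2] + 10))))
      bouts <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("onset", "end")))
      if (k > 0) {
        taken <- logical(tib)
        for (b in seq_len(k)) {
          len <- round(stats::runif(1, spec$awakening_len_range[1],
                                    spec$awakening_len_range[2]))
          for (try in 1:20) {
            s <- sample.int(tib - 60 - len, 1) + 30L
            span <- s:(s + len - 1L)
            if (!any(taken[span])) {
              taken[span] <- TRUE
              counts[idx[span]] <- draw_wake_counts(len, spec) + 1L
              bouts <- rbind(bouts, c(idx[s], idx[s + len - 1L]))
              break
            }
          }
        }
      }
      truth[[j]] <- tibble::tibble(
        night = j,
        true_in_bed = origin + 60 * bed_min,
        true_out_bed = origin + 60 * wake_min,
        awakenings = list(bouts)
      )
    }

    # optional daytime non-wear blocks (counts zero, wear FALSE)
    for (day in seq_len(n_days)) {
      if (stats::runif(1) < spec$nonwear_prob) {
        s <- (day - 1L) * 1440L + 60L + sample.int(240L, 1)  # early afternoon
        span <- (s + 1L):min(n_min, s + spec$nonwear_len)
        counts[span] <- 0L
        wear[span] <- FALSE
      }
    }

    truth <- dplyr::bind_rows(truth)
    noise_in <- round(stats::rnorm(nrow(truth), 0, spec$recall_sd))
    noise_out <- round(stats::rnorm(nrow(truth), 0, spec$recall_sd))
    in_bed <- truth$true_in_bed + 60 * noise_in
    out_bed <- truth$true_out_bed + 60 * noise_out
    short <- out_bed <= in_bed
    out_bed[short] <- in_bed[short] + 3600          # keep windows positive
    span_end <- origin + 60 * n_min
    in_bed <- pmax(origin, pmin(in_bed, span_end - 7200))
    out_bed <- pmax(in_bed + 3600, pmin(out_bed, span_end))

    list(
      epochs = epoch_series(pid, origin, counts, wear),
      log = tibble::tibble(participant_id = pid, in_bed = in_bed,
                           out_bed = out_bed),
      truth = truth
    )
  })
}

#' Write a simulated cohort to disk
#'
#' Writes one epoch CSV per participant, a combined sleep-log CSV, and a
#' ground-truth JSON file, in the formats the readers consume.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed passed to [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths (`epoch_files`,
#'   `sleep_log`, `truth`).
#' @export
simulate_cohort_files <- function(spec = cohort_spec(), seed, dir) {
  cohort <- generate_cohort(spec, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  epoch_files <- vapply(cohort, function(d) {
    path <- file.path(dir, paste0("epochs_", d$epochs$participant_id, ".csv"))
    write_epoch_csv(d$epochs, path)
    path
  }, character(1))
  log <- dplyr::bind_rows(lapply(cohort, `[[`, "log"))
  log_out <- dplyr::mutate(
    log,
    in_bed = format(.data$in_bed, "%Y-%m-%dT%H:%M:%S"),
    out_bed = format(.data$out_bed, "%Y-%m-%dT%H:%M:%S")
  )
  log_path <- file.path(dir, "sleep_log.csv")
  readr::write_csv(log_out, log_path, progress = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- lapply(cohort, function(d) {
    tr <- d$truth
    list(
      participant_id = d$epochs$participant_id,
      nights = lapply(seq_len(nrow(tr)), function(i) {
        list(
          night = tr$night[i],
          true_in_bed = format(tr$true_in_bed[i], "%Y-%m-%dT%H:%M:%S"),
          true_out_bed = format(tr$true_out_bed[i], "%Y-%m-%dT%H:%M:%S"),
          awakening_epochs = apply(tr$awakenings[[i]], 1, identity,
                                   simplify = FALSE)
        )
      })
    )
  })
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE)
  invisible(list(epoch_files = epoch_files, sleep_log = log_path,
                 truth = truth_path))
}
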