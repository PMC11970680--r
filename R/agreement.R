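# overlap (in minutes) of one interval [a, b] with a set of disjoint
# intervals given as inclusive epoch index columns onset/end
interval_overlap <- function(a, b, onset, end) {
  if (length(onset) == 0L) return(0L)
  sum(pmax(0L, pmin(b, end) - pmax(a, onset) + 1L))
}

#' Per-minute agreement between two sets of sleep periods
#'
#' The percentage of agreement is a Jaccard index over minute sets: the
#' number of one-minute epochs both methods place inside a sleep period,
#' divided by the number of epochs either method does. Minutes of
#' within-period wake count as asleep (sleep logs record no within-night
#' wake), and the statistic is computed over the whole recording span. If
#' neither method detects any sleep the statistic is undefined and returned
#' as `NA` with `defined = FALSE`.
#'
#' @param detected Period tibble from one method (e.g.
#'   [detect_sleep_periods()]).
#' @param logged Period tibble from the reference method (e.g.
#'   [periods_from_log()]).
#' @return A one-row tibble: `participant_id`, `minutes_both`,
#'   `minutes_either`, `agreement`, `defined`.
#' @export
minute_agreement <- function(detected, logged) {
  pid <- c(detected$participant_id, logged$participant_id)
  pid <- if (length(pid)) pid[1] else NA_character_
  a_total <- sum(detected$end - detected$onset + 1L)
  b_total <- sum(logged$end - logged$onset + 1L)
  both <- 0L
  if (nrow(detected) && nrow(logged)) {
    both <- sum(vapply(seq_len(nrow(detected)), function(i) {
      interval_overlap(detected$onset[i], detected$end[i],
                       logged$onset, logged$end)
    }, numeric(1)))
  }
  either <- a_total + b_total - both
  tibble::tibble(
    participant_id = pid,
    minutes_both = as.integer(both),
    minutes_either = as.integer(either),
    agreement = if (either > 0) both / either else NA_real_,
    defined = either > 0
  )
}

#' Cohort mean agreement
#'
#' Unweighted mean of per-participant agreement fractions, so participants
#' contributing more recorded nights do not dominate. Undefined participant
#' results are excluded.
#'
#' @param results Tibble of rows from [minute_agreement()].
#' @return The mean agreement fraction.
#' @export
cohort_agreement <- function(results) {
  vals <- results$agreement[results$defined]
  if (length(vals) == 0L) {
    stop("agreement is undefined for every participant", call. = FALSE)
  }
  mean(vals)
}

#' Sensitivity-analysis parameter grid
#'
#' Candidate values for the four tuned Tudor-Locke parameters; the maximum
#' period length stays at its default. The default grid enumerates
#' `6 * 6 * 7 * 6 = 1512` parameter sets.
#'
#' @param bedtime_def,waketime_def,min_period_len,min_nonzero_epochs Candidate
#'   values per parameter.
#' @param max_period_len Fixed maximum period length (minutes).
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(bedtime_def = c(5, 10, 15, 20, 25, 30),
                      waketime_def = c(5, 10, 15, 20, 25, 30),
                      min_period_len = c(30, 60, 90, 120, 150, 160, 180),
                      min_nonzero_epochs = c(0, 5, 10, 15, 20, 25),
                      max_period_len = 1440) {
  stopifnot(length(bedtime_def) >= 1, length(waketime_def) >= 1,
            length(min_period_len) >= 1, length(min_nonzero_epochs) >= 1)
  structure(
    list(bedtime_def = sort(unique(as.integer(bedtime_def))),
         waketime_def = sort(unique(as.integer(waketime_def))),
         min_period_len = sort(unique(as.integer(min_period_len))),
         min_nonzero_epochs = sort(unique(as.integer(min_nonzero_epochs))),
         max_period_len = as.integer(max_period_len)),
    class = "grid_spec"
  )
}

#' Enumerate a grid as a tibble
#'
#' Rows follow the deterministic enumeration order used for tie-breaking:
#' `bedtime_def`, then `waketime_def`, then `min_period_len`, then
#' `min_nonzero_epochs`, each ascending.
#'
#' @param grid A [grid_spec()].
#' @return A tibble of parameter sets.
#' @export
grid_rows <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  tidyr::expand_grid(
    bedtime_def = grid$bedtime_def,
    waketime_def = grid$waketime_def,
    min_period_len = grid$min_period_len,
    min_nonzero_epochs = grid$min_nonzero_epochs
  ) |>
    dplyr::mutate(max_period_len = grid$max_period_len)
}

#' Grid-search sensitivity analysis of the Tudor-Locke parameters
#'
#' For every parameter set in the grid, detects sleep periods for each
#' participant, computes the per-minute agreement against that participant's
#' sleep-log periods, and averages agreement across participants. The scan
#' structure of the detector means candidate periods depend only on
#' `bedtime_def` and `waketime_def`; the remaining parameters act as
#' per-candidate filters, which the search exploits, so results are identical
#' to running [detect_sleep_periods()] cell by cell.
#'
#' @param datasets List of participant datasets, each a list with elements
#'   `epochs` (an [epoch_series()]) and `log` (sleep-log tibble).
#' @param grid A [grid_spec()].
#' @param scorer A [ck_config()] used once per participant.
#' @return A tibble with one row per parameter set (parameters,
#'   `mean_agreement`, `n_defined`, and a `participant_agreement`
#'   list-column of named per-participant fractions), sorted by
#'   `mean_agreement` descending; ties keep enumeration order. The top row is
#'   the optimal set.
#' @export
grid_search <- function(datasets, grid = grid_spec(), scorer = ck_config()) {
  stopifnot(inherits(grid, "grid_spec"), length(datasets) >= 1)
  rows <- grid_rows(grid)
  n_rows <- nrow(rows)
  if (n_rows == 0L) stop("empty parameter grid", call. = FALSE)

  filters <- tidyr::expand_grid(
    min_period_len = grid$min_period_len,
    min_nonzero_epochs = grid$min_nonzero_epochs
  )
  n_filt <- nrow(filters)

  pids <- vapply(datasets, function(d) d$epochs$participant_id, character(1))
  agree <- matrix(NA_real_, nrow = n_rows, ncol = length(datasets),
                  dimnames = list(NULL, pids))

  for (p in seq_along(datasets)) {
    d <- datasets[[p]]
    sw <- score_cole_kripke(d$epochs, scorer)
    logp <- periods_from_log(d$log, d$epochs)
    log_total <- sum(logp$duration_min)
    nz_cum <- c(0L, cumsum(d$epochs$counts >= 1L))
    row0 <- 0L
    for (bt in grid$bedtime_def) {
      for (wt in grid$waketime_def) {
        cand <- tl_candidates(sw$asleep, bt, wt)
        if (nrow(cand)) {
          dur <- cand[, "end"] - cand[, "onset"] + 1L
          nz <- nz_cum[cand[, "end"] + 1L] - nz_cum[cand[, "onset"]]
          ov <- vapply(seq_len(nrow(cand)), function(i) {
            interval_overlap(cand[i, "onset"], cand[i, "end"],
                             logp$onset, logp$end)
          }, numeric(1))
        }
        for (f in seq_len(n_filt)) {
          ml <- filters$min_period_len[f]
          mnz <- filters$min_nonzero_epochs[f]
          if (nrow(cand)) {
            keep <- dur >= ml & dur < grid$max_period_len & nz >= mnz
            both <- sum(ov[keep])
            either <- sum(dur[keep]) + log_total - both
          } else {
            both <- 0
            either <- log_total
          }
          agree[row0 + f, p] <- if (either > 0) both / either else NA_real_
        }
        row0 <- row0 + n_filt
      }
    }
  }

  rows$mean_agreement <- apply(agree, 1L, function(a) {
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  })
  rows$n_defined <- apply(agree, 1L, function(a) sum(!is.na(a)))
  rows$participant_agreement <- lapply(seq_len(n_rows), function(i) agree[i, ])
  dplyr::arrange(rows, dplyr::desc(.data$mean_agreement))
}

#' Optimal parameter set of a grid-search result
#'
#' @param result Output of [grid_search()].
#' @return A [tl_params()] built from the top-ranked row.
#' @export
best_params <- function(result) {
  top <- result[1, ]
  tl_params(top$bedtime_def, top$waketime_def, top$min_period_len,
            top$min_nonzero_epochs, top$max_period_len)
}

#' Marginal parameter effects of a grid search
#'
#' For each tuned parameter, averages the mean agreement over all grid rows
#' sharing a value, and ranks parameters by the range of those marginal
#' means.
#'
#' @param result Output of [grid_search()].
#' @return A list: `marginals` (tibble of parameter, value, mean agreement),
#'   `ranges` (tibble of parameter, marginal range, descending), and
#'   `most_influential` (name of the parameter with the largest range).
#' @export
summarize_parameter_effects <- function(result) {
  params <- c("bedtime_def", "waketime_def", "min_period_len",
              "min_nonzero_epochs")
  marginals <- purrr::map_dfr(params, function(pn) {
    result |>
      dplyr::group_by(value = .data[[pn]]) |>
      dplyr::summarise(
        mean_agreement = mean(.data$mean_agreement, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(parameter = pn, .before = 1)
  })
  ranges <- marginals |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      range = max(.data$mean_agreement) - min(.data$mean_agreement),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$range))
  list(
    marginals = marginals,
    ranges = ranges,
    most_influential = ranges$parameter[1]
  )
}
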