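test_that("agreement is a Jaccard index over minute sets", {
  a <- dplyr::bind_rows(period_row(100, 579), period_row(1540, 2019))
  expect_equal(minute_agreement(a, a)$agreement, 1)

  b <- dplyr::bind_rows(period_row(700, 899))
  expect_equal(minute_agreement(a, b)$agreement, 0)

  # detected period fully inside a 480-minute log window, covering 420 minutes
  log <- period_row(100, 579, source = "LOG")
  det <- period_row(130, 549)
  expect_equal(minute_agreement(det, log)$agreement, 420 / 480)

  # failing to detect any sleep scores zero against a non-empty log
  none <- minute_agreement(period_row(1, 1)[0, ], log)
  expect_equal(none$agreement, 0)
  expect_true(none$defined)

  # both empty: undefined, flagged
  und <- minute_agreement(period_row(1, 1)[0, ], period_row(1, 1)[0, ])
  expect_true(is.na(und$agreement))
  expect_false(und$defined)
})

test_that("agreement is symmetric, bounded, and penalized by spurious periods", {
  set.seed(41)
  for (rep in 1:30) {
    n <- 3000
    mk <- function() {
      k <- sample(1:4, 1)
      starts <- sort(sample(seq(1, n - 400, by = 50), k))
      dplyr::bind_rows(lapply(starts, function(s) {
        period_row(s, min(n, s + sample(50:300, 1)))
      }))
    }
    a <- mk()
    b <- mk()
    # intervals within one method must be disjoint for a valid period list
    collapse <- function(p) {
      p <- p[order(p$onset), ]
      keep <- c(TRUE, p$onset[-1] > cummax(p$end[-nrow(p)]))
      p[keep, ]
    }
    a <- collapse(a)
    b <- collapse(b)
    ab <- minute_agreement(a, b)
    ba <- minute_agreement(b, a)
    expect_equal(ab$agreement, ba$agreement)
    expect_true(ab$agreement >= 0 && ab$agreement <= 1)
    o <- oracle_agreement(a, b, n)
    expect_equal(ab$minutes_both, o$both, ignore_attr = TRUE)
    expect_equal(ab$minutes_either, o$either, ignore_attr = TRUE)
    expect_equal(ab$agreement, o$agreement)
    # adding a detected period disjoint from everything strictly lowers it
    if (max(a$end, b$end) < n - 200 && ab$agreement > 0) {
      a2 <- dplyr::bind_rows(a, period_row(n - 150, n - 50))
      if (all(n - 150 > b$end)) {
        expect_lt(minute_agreement(a2, b)$agreement, ab$agreement)
      }
    }
  }
})

test_that("cohort agreement is the unweighted participant mean", {
  mk <- function(vals) {
    tibble::tibble(participant_id = as.character(seq_along(vals)),
                   minutes_both = 1L, minutes_either = 1L,
                   agreement = vals, defined = !is.na(vals))
  }
  expect_equal(cohort_agreement(mk(c(1, 0.5))), 0.75)
  expect_equal(cohort_agreement(mk(0.67)), 0.67)
  expect_equal(cohort_agreement(mk(c(0.9, 0.6, 0))), 0.5)
  # undefined participants are excluded from the mean
  expect_equal(cohort_agreement(mk(c(0.8, NA, 0.4))), 0.6)
  expect_error(cohort_agreement(mk(c(NA_real_, NA_real_))), "undefined")
})

test_that("the default grid enumerates 1512 parameter sets in tie-break order", {
  rows <- grid_rows(grid_spec())
  expect_equal(nrow(rows), 1512)
  expect_equal(nrow(dplyr::distinct(rows)), 1512)
  # lexicographic: bedtime_def, waketime_def, min_period_len, min_nonzero
  expect_true(!is.unsorted(rows$bedtime_def))
  first_block <- rows[rows$bedtime_def == 5, ]
  expect_true(!is.unsorted(first_block$waketime_def))
})

test_that("a degenerate one-cell grid equals a direct single run", {
  cohort <- generate_cohort(cohort_spec(n_participants = 3,
                                        nights_per_participant = 5),
                            seed = 5)
  g1 <- grid_spec(bedtime_def = 5, waketime_def = 25, min_period_len = 160,
                  min_nonzero_epochs = 5)
  res <- grid_search(cohort, g1)
  expect_equal(nrow(res), 1)
  direct <- sapply(cohort, function(d) {
    sw <- score_cole_kripke(d$epochs)
    minute_agreement(detect_sleep_periods(sw, d$epochs, tl_chronic_pain()),
                     periods_from_log(d$log, d$epochs))$agreement
  })
  expect_equal(res$mean_agreement, mean(direct))
  expect_error(grid_search(list(), g1))
})

test_that("grid search equals cell-by-cell detection and is deterministic", {
  cohort <- generate_cohort(cohort_spec(n_participants = 2,
                                        nights_per_participant = 5),
                            seed = 9)
  grid <- grid_spec(bedtime_def = c(5, 15), waketime_def = c(5, 10, 25),
                    min_period_len = c(30, 160), min_nonzero_epochs = c(0, 10))
  res <- grid_search(cohort, grid)
  expect_equal(nrow(res), 2 * 3 * 2 * 2)
  res2 <- grid_search(cohort, grid)
  expect_identical(res$mean_agreement, res2$mean_agreement)

  scored <- lapply(cohort, function(d) score_cole_kripke(d$epochs))
  for (i in seq_len(nrow(res))) {
    ags <- sapply(seq_along(cohort), function(p) {
      prm <- tl_params(res$bedtime_def[i], res$waketime_def[i],
                       res$min_period_len[i], res$min_nonzero_epochs[i],
                       res$max_period_len[i])
      det <- detect_sleep_periods(scored[[p]], cohort[[p]]$epochs, prm)
      minute_agreement(det,
                       periods_from_log(cohort[[p]]$log,
                                        cohort[[p]]$epochs))$agreement
    })
    expect_equal(res$mean_agreement[i], mean(ags, na.rm = TRUE))
  }
})

test_that("marginal parameter effects summarize the grid", {
  fake <- grid_rows(grid_spec(bedtime_def = c(5, 10), waketime_def = 5,
                              min_period_len = 160, min_nonzero_epochs = 0))
  fake$mean_agreement <- c(0.4, 0.6)
  eff <- summarize_parameter_effects(fake)
  bt <- eff$marginals[eff$marginals$parameter == "bedtime_def", ]
  expect_equal(sort(bt$mean_agreement), c(0.4, 0.6))
  expect_equal(eff$ranges$range[eff$ranges$parameter == "bedtime_def"], 0.2)
  # constant parameters have zero marginal range
  expect_equal(eff$ranges$range[eff$ranges$parameter == "waketime_def"], 0)
  expect_equal(eff$most_influential, "bedtime_def")
})
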