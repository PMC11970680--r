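# small paired daily fixture: 3 participants x 3 days, two methods
fixture_paired <- function() {
  daily <- function(vals, pid, days) {
    tibble::tibble(
      participant_id = pid, day = as.Date("2023-03-01") + days - 1,
      n_periods = 1L, latency = 0L, efficiency = 90, tib = vals,
      tst = as.integer(round(vals * 0.9)), waso = 10L, n_awakenings = 2L,
      avg_awakening_len = 5, movement_index = 10, fragmentation_index = 5,
      sleep_fragmentation_index = 15
    )
  }
  a <- dplyr::bind_rows(daily(c(400L, 440L, 420L), "P1", 1:3),
                        daily(c(500L, 480L, 510L), "P2", 1:3),
                        daily(c(450L, 450L, 460L), "P3", 1:3))
  b <- a
  b$tib <- b$tib + 20L
  list(SL = a, TL = b)
}

test_that("the paired table keys on (participant, day) with NA for missed days", {
  methods <- fixture_paired()
  methods$TL <- methods$TL[-2, ]     # TL misses P1 day 2
  paired <- paired_daily_table(methods)
  expect_equal(nrow(paired), 9)
  expect_equal(sum(is.na(paired$tib_TL)), 1)
  expect_equal(sum(is.na(paired$tib_SL)), 0)
  expect_equal(anyDuplicated(paired[, c("participant_id", "day")]), 0L)
})

test_that("missed-night accounting reproduces the report structure", {
  methods <- fixture_paired()
  full <- paired_daily_table(methods)
  r0 <- missed_night_report(full, "TL")
  expect_equal(r0$n_missed_days, 0)
  expect_equal(r0$n_participants, 0)

  methods$TL <- methods$TL[-c(2, 7), ]   # one miss each for P1 and P3
  paired <- paired_daily_table(methods)
  r <- missed_night_report(paired, "TL", reference = "SL")
  expect_equal(r$n_missed_days, 2)
  expect_equal(r$pct_missed_days, 100 * 2 / 9)
  expect_equal(r$n_participants, 2)
  expect_equal(r$pct_participants, 100 * 2 / 3)
  expect_equal(r$mean_missed_per_affected, 1)
})

test_that("missing-data strategies behave and coincide when fully observed", {
  methods <- fixture_paired()
  full <- paired_daily_table(methods)
  expect_equal(apply_missing_strategy(full, "complete_case"),
               apply_missing_strategy(full, "zero_impute"))

  methods$TL <- methods$TL[-2, ]
  paired <- paired_daily_table(methods)
  cc <- apply_missing_strategy(paired, "complete_case")
  zi <- apply_missing_strategy(paired, "zero_impute")
  expect_equal(nrow(cc), 8)
  expect_equal(nrow(zi), 9)
  expect_equal(zi$tib_TL[is.na(paired$tib_TL)], 0)
  expect_error(apply_missing_strategy(paired, "drop_everything"))
})

test_that("participant means average observed days; zero imputation biases them", {
  methods <- fixture_paired()
  methods$TL$tib <- c(400L, 440L, 420L, 500L, 480L, 510L, 450L, 450L, 460L)
  methods$TL <- methods$TL[-3, ]   # P1 loses the 420 day
  paired <- paired_daily_table(methods)
  cc <- participant_means(apply_missing_strategy(paired, "complete_case"),
                          "tib", "TL")
  expect_equal(cc$mean_value[cc$participant_id == "P1"], mean(c(400, 440)))
  zi <- participant_means(apply_missing_strategy(paired, "zero_impute"),
                          "tib", "TL")
  expect_equal(zi$mean_value[zi$participant_id == "P1"],
               mean(c(400, 440, 0)))
  expect_equal(zi$mean_value[zi$participant_id == "P1"], 280)
})

test_that("Bland-Altman: identical methods give zero bias and zero-width limits", {
  methods <- fixture_paired()
  methods$TL <- methods$SL
  paired <- paired_daily_table(methods)
  res <- extended_bland_altman(paired, "tib", c("TL", "SL"))
  expect_equal(res$mean_bias, 0)
  expect_equal(res$loa_low, 0)
  expect_equal(res$loa_high, 0)
})

test_that("a constant offset is recovered exactly, and swapping negates it", {
  paired <- paired_daily_table(fixture_paired())   # TL = SL + 20
  res <- extended_bland_altman(paired, "tib", c("TL", "SL"))
  expect_equal(res$mean_bias, 20)
  expect_equal(res$loa_low, 20)
  expect_equal(res$loa_high, 20)
  rev <- extended_bland_altman(paired, "tib", c("SL", "TL"))
  expect_equal(rev$mean_bias, -20)
  expect_equal(rev$loa_low, -res$loa_high)
  expect_equal(rev$loa_high, -res$loa_low)
})

test_that("Bland-Altman recovers simulated variance components", {
  set.seed(52)
  k <- 50
  reps <- 5
  subj_eff <- rnorm(k, mean = 5, sd = 3)
  d <- rep(subj_eff, each = reps) + rnorm(k * reps, sd = 4)
  paired <- tibble::tibble(
    participant_id = rep(sprintf("S%02d", 1:k), each = reps),
    day = as.Date("2023-03-01") + rep(1:reps, k),
    x_A = d, x_B = 0
  )
  res <- extended_bland_altman(paired, "x", c("A", "B"))
  expect_equal(res$mean_bias, 5, tolerance = 1 / 5)        # absolute ~1
  half_width <- (res$loa_high - res$loa_low) / 2
  expect_equal(half_width, 1.96 * sqrt(3^2 + 4^2), tolerance = 0.1)
  expect_equal(sqrt(res$within_subject_var), 4, tolerance = 0.15)
  expect_equal(sqrt(res$between_subject_var), 3, tolerance = 0.4)
})

test_that("Bland-Altman needs at least two subjects", {
  paired <- tibble::tibble(participant_id = "P1",
                           day = as.Date("2023-03-01") + 1:4,
                           x_A = rnorm(4), x_B = rnorm(4))
  expect_error(extended_bland_altman(paired, "x", c("A", "B")), "two subjects")
})

test_that("exact Wilcoxon p equals sign-assignment enumeration", {
  # five positive untied differences: p = 2 / 2^5
  res <- wilcoxon_signed_rank(c(11, 12, 13, 14, 15), c(10, 10, 10, 10, 10))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 15)

  # mixed signs, checked against brute-force enumeration over 16 assignments
  a <- c(0, 2, 0, 4)
  b <- c(1, 0, 3, 0)
  res2 <- wilcoxon_signed_rank(a, b)
  expect_equal(res2$p_value, oracle_wilcoxon_p(a - b))

  # identical vectors: degenerate, p = 1
  res3 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$p_value, 1)
  expect_equal(res3$n_effective, 0L)
  expect_equal(res3$method, "degenerate")
})

test_that("exact p matches enumeration for random untied cases up to n = 12", {
  set.seed(53)
  for (n in c(3, 5, 8, 10, 12)) {
    for (rep in 1:6) {
      d <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 10)
      res <- wilcoxon_signed_rank(d, rep(0, n))
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, oracle_wilcoxon_p(d))
    }
  }
})

test_that("ties or large n fall back to the corrected normal approximation", {
  d <- c(1, 1, 2, -2, 3, -3, 4, 5, 5, -6)
  res <- wilcoxon_signed_rank(d, rep(0, 10))
  expect_equal(res$method, "approximate")
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE))
  expect_equal(res$p_value, ref$p.value)

  set.seed(54)
  d30 <- rnorm(30)
  res30 <- wilcoxon_signed_rank(d30, rep(0, 30))
  expect_equal(res30$method, "approximate")
  expect_true(res30$p_value >= 0 && res30$p_value <= 1)
})

test_that("exact test keeps type-I error at or below nominal level", {
  set.seed(55)
  n <- 10
  reps <- 400
  rejections <- 0
  for (r in seq_len(reps)) {
    d <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 10)
    if (wilcoxon_signed_rank(d, rep(0, n))$p_value <= 0.05) {
      rejections <- rejections + 1
    }
  }
  # exact test is conservative; allow Monte-Carlo slack above 0.05
  expect_lt(rejections / reps, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})
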