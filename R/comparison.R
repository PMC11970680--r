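#' Paired daily measure table across methods
#'
#' Joins daily-aggregated measures from several detection methods into one
#' table keyed by (participant, day). Cells are `NA` exactly where a method
#' detected no sleep period that day; measure columns are suffixed with the
#' method name (e.g. `tst_SL`, `tst_TLD`).
#'
#' @param daily_by_method Named list of daily tibbles (from
#'   [aggregate_daily()]), one per method, e.g.
#'   `list(SL = ..., TLD = ..., TLO = ...)`.
#' @return A wide tibble with one row per (participant, day) observed by any
#'   method.
#' @export
paired_daily_table <- function(daily_by_method) {
  stopifnot(is.list(daily_by_method), length(daily_by_method) >= 2,
            !is.null(names(daily_by_method)))
  long <- purrr::imap_dfr(daily_by_method, function(df, method) {
    df |>
      dplyr::select(dplyr::all_of(c("participant_id", "day",
                                    measure_names()))) |>
      dplyr::mutate(method = method)
  })
  tidyr::pivot_wider(
    long,
    id_cols = c("participant_id", "day"),
    names_from = "method",
    values_from = dplyr::all_of(measure_names()),
    names_sep = "_"
  ) |>
    dplyr::arrange(.data$participant_id, .data$day)
}

#' Missed-night accounting for a detection method
#'
#' Counts reference nights (rows where the reference method has an observed
#' value) on which `method` detected no sleep period, and summarizes how many
#' participants are affected.
#'
#' @param paired Output of [paired_daily_table()].
#' @param method Method name to audit (e.g. `"TLD"`).
#' @param reference Reference method defining the night universe (default
#'   `"SL"`).
#' @return A list: `n_missed_days`, `pct_missed_days`, `n_participants`,
#'   `pct_participants`, `mean_missed_per_affected`, `sd_missed_per_affected`.
#' @export
missed_night_report <- function(paired, method, reference = "SL") {
  ref_col <- paste0("tib_", reference)
  m_col <- paste0("tib_", method)
  stopifnot(ref_col %in% names(paired), m_col %in% names(paired))
  nights <- paired[!is.na(paired[[ref_col]]), , drop = FALSE]
  missed <- nights[is.na(nights[[m_col]]), , drop = FALSE]
  per_pid <- table(missed$participant_id)
  n_pid_total <- length(unique(paired$participant_id))
  list(
    n_missed_days = nrow(missed),
    pct_missed_days = if (nrow(nights)) 100 * nrow(missed) / nrow(nights)
                      else 0,
    n_participants = length(per_pid),
    pct_participants = if (n_pid_total) 100 * length(per_pid) / n_pid_total
                       else 0,
    mean_missed_per_affected = if (length(per_pid)) mean(per_pid) else 0,
    sd_missed_per_affected = if (length(per_pid) > 1) stats::sd(per_pid)
                             else NA_real_
  )
}

#' Apply a missing-data strategy
#'
#' `complete_case` drops rows with any missing cell among the compared
#' method-measure columns; `zero_impute` replaces missing cells with zero.
#' The two strategies coincide on fully observed tables.
#'
#' @param paired Output of [paired_daily_table()].
#' @param strategy `"complete_case"` or `"zero_impute"`.
#' @param methods Methods whose columns participate (default: all methods in
#'   the table).
#' @param measures Measures considered (default: all ten).
#' @return The filtered or imputed table.
#' @export
apply_missing_strategy <- function(paired,
                                   strategy = c("complete_case",
                                                "zero_impute"),
                                   methods = NULL, measures = measure_names()) {
  strategy <- match.arg(strategy)
  if (is.null(methods)) {
    methods <- unique(sub(
      paste0("^(", paste(measure_names(), collapse = "|"), ")_"), "",
      setdiff(names(paired), c("participant_id", "day"))
    ))
  }
  cols <- as.vector(outer(measures, methods, paste, sep = "_"))
  cols <- intersect(cols, names(paired))
  if (strategy == "complete_case") {
    keep <- stats::complete.cases(paired[, cols, drop = FALSE])
    paired[keep, , drop = FALSE]
  } else {
    paired |>
      dplyr::mutate(dplyr::across(dplyr::all_of(cols),
                                  \(x) tidyr::replace_na(x, 0)))
  }
}

#' Per-participant means of a daily measure
#'
#' @param paired Output of [paired_daily_table()] (after
#'   [apply_missing_strategy()]).
#' @param measure One of [measure_names()].
#' @param method Method name.
#' @return A tibble `participant_id`, `mean_value`, `n_days`. Participants
#'   with no observed day are excluded with a warning.
#' @export
participant_means <- function(paired, measure, method) {
  col <- paste0(measure, "_", method)
  stopifnot(col %in% names(paired))
  out <- paired |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      mean_value = mean(.data[[col]], na.rm = TRUE),
      n_days = sum(!is.na(.data[[col]])),
      .groups = "drop"
    )
  if (any(out$n_days == 0)) {
    warning("participant(s) with no observed days excluded: ",
            paste(out$participant_id[out$n_days == 0], collapse = ", "),
            call. = FALSE)
    out <- out[out$n_days > 0, , drop = FALSE]
  }
  out
}

#' Bland-Altman limits of agreement for repeated measures
#'
#' Limits of agreement between two methods when each subject contributes
#' several paired days and the true quantity varies from day to day. The
#' variance of a single between-method difference is partitioned by a one-way
#' random-effects ANOVA on subjects: the within-subject component is the
#' residual mean square, the between-subject component is
#' `(MSB - MSW) / n0` (floored at zero) with `n0` the standard
#' unequal-replicates divisor `(N - sum(n_i^2)/N) / (k - 1)`. The 95% limits
#' are `bias +/- 1.96 * sqrt(between + within)`. When every subject
#' contributes a single difference the split is unidentifiable and the
#' classic single-level limits (`sd` of the differences) are used, with the
#' components reported as `NA`.
#'
#' @param paired Output of [paired_daily_table()]; complete-case filtering is
#'   applied to the two columns involved.
#' @param measure One of [measure_names()].
#' @param method_pair Character vector of two method names; differences are
#'   `first - second`.
#' @return A list: `measure`, `method_pair`, `n_obs`, `n_subjects`,
#'   `mean_bias`, `loa_low`, `loa_high`, `sd_difference`,
#'   `between_subject_var`, `within_subject_var`.
#' @export
extended_bland_altman <- function(paired, measure, method_pair) {
  stopifnot(length(method_pair) == 2)
  col_a <- paste0(measure, "_", method_pair[1])
  col_b <- paste0(measure, "_", method_pair[2])
  stopifnot(col_a %in% names(paired), col_b %in% names(paired))
  ok <- !is.na(paired[[col_a]]) & !is.na(paired[[col_b]])
  d <- paired[[col_a]][ok] - paired[[col_b]][ok]
  subj <- factor(paired$participant_id[ok])
  k <- nlevels(subj)
  if (k < 2) {
    stop("at least two subjects are required to estimate the ",
         "between-subject component", call. = FALSE)
  }
  n_i <- as.vector(table(subj))
  n_tot <- sum(n_i)
  bias <- mean(d)
  if (n_tot - k == 0L) {
    # one difference per subject: no replication, classic limits
    sd_d <- stats::sd(d)
    between <- NA_real_
    within <- NA_real_
    message("one observation per subject; reporting classic limits of ",
            "agreement")
  } else {
    # only the mean squares are used; the F-test (meaningless on, e.g., an
    # exact constant offset) is discarded
    av <- suppressWarnings(stats::anova(stats::aov(d ~ subj)))
    msb <- av[["Mean Sq"]][1]
    msw <- av[["Mean Sq"]][2]
    n0 <- (n_tot - sum(n_i^2) / n_tot) / (k - 1)
    between <- max(0, (msb - msw) / n0)
    within <- msw
    sd_d <- sqrt(between + within)
  }
  list(
    measure = measure,
    method_pair = method_pair,
    n_obs = n_tot,
    n_subjects = k,
    mean_bias = bias,
    loa_low = bias - 1.96 * sd_d,
    loa_high = bias + 1.96 * sd_d,
    sd_difference = sd_d,
    between_subject_var = between,
    within_subject_var = within
  )
}

#' Wilcoxon signed-rank test on paired participant means
#'
#' Two-sided signed-rank test of paired differences. Zero differences are
#' dropped (classical treatment); the exact null distribution is used when at
#' most 25 non-zero differences remain and their absolute values are untied,
#' otherwise the normal approximation with tie and continuity corrections.
#' When every difference is zero the test is degenerate and `p = 1` is
#' reported with `n_effective = 0`.
#'
#' @param means_a,means_b Numeric vectors of equal length, paired by
#'   participant.
#' @return A list: `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_effective`, `method` (`"exact"`, `"approximate"` or `"degenerate"`).
#' @export
wilcoxon_signed_rank <- function(means_a, means_b) {
  stopifnot(length(means_a) == length(means_b), length(means_a) >= 2,
            !anyNA(means_a), !anyNA(means_b))
  d <- means_a - means_b
  dd <- d[d != 0]
  n_eff <- length(dd)
  if (n_eff == 0L) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  ties <- anyDuplicated(abs(dd)) > 0
  use_exact <- n_eff <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(dd, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_effective = n_eff,
    method = if (use_exact) "exact" else "approximate"
  )
}

#' Pairwise Wilcoxon comparisons of all measures
#'
#' Runs [wilcoxon_signed_rank()] on per-participant mean sleep measures for
#' each measure and each method pair. Pairs whose differences are identically
#' zero by construction (e.g. latency between two Tudor-Locke variants) are
#' reported as degenerate rather than tested.
#'
#' @param paired Output of [paired_daily_table()] after a missing-data
#'   strategy.
#' @param method_pairs List of 2-vectors of method names.
#' @param measures Measures to compare (default all ten).
#' @return Tibble: measure, method_a, method_b, statistic, p_value,
#'   n_effective, method.
#' @export
compare_measures_wilcoxon <- function(paired, method_pairs,
                                      measures = measure_names()) {
  purrr::map_dfr(method_pairs, function(pair) {
    purrr::map_dfr(measures, function(m) {
      a <- participant_means(paired, m, pair[1])
      b <- participant_means(paired, m, pair[2])
      joined <- dplyr::inner_join(a, b, by = "participant_id",
                                  suffix = c("_a", "_b"))
      res <- wilcoxon_signed_rank(joined$mean_value_a, joined$mean_value_b)
      tibble::tibble(
        measure = m, method_a = pair[1], method_b = pair[2],
        statistic = res$statistic, p_value = res$p_value,
        n_effective = res$n_effective, method = res$method
      )
    })
  })
}

#' Bland-Altman tables for all measures
#'
#' @param paired Output of [paired_daily_table()].
#' @param method_pairs List of 2-vectors of method names (differences are
#'   `first - second`).
#' @param measures Measures to compare.
#' @return Tibble: one row per (measure, pair) with bias and 95% limits.
#' @export
compare_measures_bland_altman <- function(paired, method_pairs,
                                          measures = measure_names()) {
  purrr::map_dfr(method_pairs, function(pair) {
    purrr::map_dfr(measures, function(m) {
      res <- extended_bland_altman(paired, m, pair)
      tibble::tibble(
        measure = m, method_a = pair[1], method_b = pair[2],
        mean_bias = res$mean_bias, loa_low = res$loa_low,
        loa_high = res$loa_high, n_obs = res$n_obs,
        n_subjects = res$n_subjects
      )
    })
  })
}
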