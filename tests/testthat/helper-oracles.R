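# Independent brute-force reference implementations used to cross-check the
# package. These deliberately share no code with the package internals:
# per-epoch loops and explicit boolean minute sets instead of run-length
# encodings and interval arithmetic.

# weighted-window sleep/wake scorer, naive per-epoch loop with zero padding
oracle_score <- function(counts, weights = c(106, 54, 58, 76, 230, 74, 67),
                         center = 5, scale = 0.001, threshold = 1) {
  n <- length(counts)
  offsets <- seq_along(weights) - center
  vapply(seq_len(n), function(t) {
    d <- 0
    for (k in seq_along(weights)) {
      src <- t + offsets[k]
      a <- if (src >= 1 && src <= n) counts[src] else 0
      d <- d + weights[k] * a
    }
    scale * d < threshold
  }, logical(1))
}

# sleep-period scanner, epoch-by-epoch with window checks
oracle_detect <- function(asleep, counts, params) {
  n <- length(asleep)
  out <- NULL
  pos <- 1L
  repeat {
    onset <- NA_integer_
    s <- pos
    while (s + params$bedtime_def - 1L <= n) {
      if (all(asleep[s:(s + params$bedtime_def - 1L)])) {
        onset <- s
        break
      }
      s <- s + 1L
    }
    if (is.na(onset)) break
    term <- NA_integer_
    t <- onset + 1L
    while (t + params$waketime_def - 1L <= n) {
      if (all(!asleep[t:(t + params$waketime_def - 1L)])) {
        term <- t
        break
      }
      t <- t + 1L
    }
    if (is.na(term)) {
      end <- max(which(asleep[onset:n])) + onset - 1L
    } else {
      end <- max(which(asleep[onset:(term - 1L)])) + onset - 1L
    }
    dur <- end - onset + 1L
    nz <- sum(counts[onset:end] >= 1)
    if (dur >= params$min_period_len && dur < params$max_period_len &&
        nz >= params$min_nonzero_epochs) {
      out <- rbind(out, c(onset, end))
    }
    if (is.na(term)) break
    pos <- term
    while (pos <= n && !asleep[pos]) pos <- pos + 1L
    if (pos > n) break
  }
  if (is.null(out)) {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "end")))
  } else {
    dimnames(out) <- list(NULL, c("onset", "end"))
    out
  }
}

# run-length sleep measures by explicit iteration
oracle_measures <- function(asleep, counts) {
  tib <- length(asleep)
  first_sleep <- NA_integer_
  for (i in seq_len(tib)) {
    if (asleep[i]) {
      first_sleep <- i
      break
    }
  }
  if (is.na(first_sleep)) {
    latency <- tib
    tst <- waso <- n_awake <- nruns <- runs1 <- 0L
  } else {
    latency <- first_sleep - 1L
    tst <- 0L
    waso <- 0L
    n_awake <- 0L
    nruns <- 0L
    runs1 <- 0L
    run_len <- 0L
    run_sleep <- NA
    for (i in first_sleep:tib) {
      if (asleep[i]) tst <- tst + 1L else waso <- waso + 1L
      if (is.na(run_sleep) || asleep[i] != run_sleep) {
        if (!is.na(run_sleep)) {
          if (run_sleep) {
            nruns <- nruns + 1L
            if (run_len == 1L) runs1 <- runs1 + 1L
          } else {
            n_awake <- n_awake + 1L
          }
        }
        run_sleep <- asleep[i]
        run_len <- 1L
      } else {
        run_len <- run_len + 1L
      }
    }
    if (run_sleep) {
      nruns <- nruns + 1L
      if (run_len == 1L) runs1 <- runs1 + 1L
    } else {
      n_awake <- n_awake + 1L
    }
  }
  mi <- 100 * sum(counts >= 1) / tib
  fi <- if (nruns > 0) 100 * runs1 / nruns else 0
  list(latency = latency, tib = tib, tst = tst, waso = waso,
       n_awakenings = n_awake,
       avg_awakening_len = if (n_awake > 0) waso / n_awake else 0,
       efficiency = 100 * tst / tib, movement_index = mi,
       fragmentation_index = fi, sleep_fragmentation_index = mi + fi)
}

# minute-set agreement via explicit boolean vectors
oracle_agreement <- function(detected, logged, n) {
  a <- rep(FALSE, n)
  b <- rep(FALSE, n)
  for (i in seq_len(nrow(detected))) a[detected$onset[i]:detected$end[i]] <- TRUE
  for (i in seq_len(nrow(logged))) b[logged$onset[i]:logged$end[i]] <- TRUE
  both <- sum(a & b)
  either <- sum(a | b)
  list(both = both, either = either,
       agreement = if (either > 0) both / either else NA_real_)
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
oracle_wilcoxon_p <- function(d) {
  dd <- d[d != 0]
  n <- length(dd)
  r <- rank(abs(dd))
  v_obs <- sum(r[dd > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  mean_v <- n * (n + 1) / 4
  p <- if (v_obs > mean_v) 2 * mean(v_null >= v_obs) else 2 * mean(v_null <= v_obs)
  min(p, 1)
}

# random sleep/wake series with persistent runs (two-state Markov chain)
random_states <- function(n, p_stay = 0.9) {
  s <- logical(n)
  s[1] <- runif(1) < 0.5
  flips <- runif(n - 1) > p_stay
  for (i in seq_len(n - 1)) s[i + 1] <- if (flips[i]) !s[i] else s[i]
  s
}

# counts loosely consistent with states: wake epochs active, sleep mostly zero
random_counts <- function(asleep) {
  n <- length(asleep)
  counts <- integer(n)
  counts[!asleep] <- rpois(sum(!asleep), 150)
  mv <- asleep & runif(n) < 0.15
  counts[mv] <- 1L + rpois(sum(mv), 2)
  counts
}

make_series <- function(asleep, counts = NULL, pid = "T") {
  if (is.null(counts)) counts <- integer(length(asleep))
  t0 <- as.POSIXct("2023-03-01 00:00:00", tz = "UTC")
  list(
    epochs = epoch_series(pid, t0, counts),
    sw = sleep_wake_series(pid, t0, asleep)
  )
}

period_row <- function(onset, end, pid = "T", source = "TL") {
  tibble::tibble(participant_id = pid, onset = as.integer(onset),
                 end = as.integer(end),
                 duration_min = as.integer(end - onset + 1L), source = source)
}

# shared cache of restless-preset grid searches over 20 seeds; computed once
# per test session and reused by the synthetic-data and acceptance tests
restless_grid_cache <- new.env(parent = emptyenv())
restless_grid_results <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (is.null(restless_grid_cache[[key]])) {
    restless_grid_cache[[key]] <- lapply(seeds, function(s) {
      cohort <- generate_cohort(chronic_pain_preset(), seed = s)
      grid_search(cohort, grid_spec())
    })
  }
  restless_grid_cache[[key]]
}

# mean agreement of a specific parameter set, looked up in a grid result
grid_cell_agreement <- function(result, bt, wt, ml, mnz) {
  row <- result[result$bedtime_def == bt & result$waketime_def == wt &
                  result$min_period_len == ml &
                  result$min_nonzero_epochs == mnz, ]
  row$mean_agreement[1]
}
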