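#' Cole-Kripke scorer configuration
#'
#' The minute-epoch Cole-Kripke score of epoch `t` is a weighted sum of
#' activity counts over a window centred (asymmetrically) on `t`:
#' `D(t) = scale * sum_k w_k * A(t + k)`, with offsets running from
#' `-(center - 1)` to `length(weights) - center`. The epoch is scored asleep
#' when `D(t) < threshold`. The defaults are the published minute-mode
#' coefficients: four epochs before, the current epoch, and two after.
#'
#' @param weights Window weights, ordered from the earliest offset.
#' @param center 1-based position of the current epoch within `weights`
#'   (default 5, i.e. offsets -4..+2).
#' @param scale Multiplier applied to the weighted sum (default 0.001).
#' @param threshold Sleep threshold; asleep iff score `< threshold`
#'   (default 1). Must be positive.
#' @param count_cap Optional per-epoch cap applied to counts before scoring
#'   (default `Inf`, i.e. counts are used as provided).
#' @return A list of class `ck_config`.
#' @export
ck_config <- function(weights = c(106, 54, 58, 76, 230, 74, 67),
                      center = 5, scale = 0.001, threshold = 1,
                      count_cap = Inf) {
  stopifnot(length(weights) >= 1, !anyNA(weights),
            center >= 1, center <= length(weights),
            is.numeric(scale), length(scale) == 1,
            is.numeric(threshold), threshold > 0,
            count_cap > 0)
  structure(
    list(weights = as.numeric(weights), center = as.integer(center),
         scale = scale, threshold = threshold, count_cap = count_cap),
    class = "ck_config"
  )
}

#' Score each epoch as sleep or wake (Cole-Kripke)
#'
#' Stage one of the pipeline: classifies every one-minute epoch of an
#' activity-count series as sleep or wake using the weighted-window
#' Cole-Kripke rule. Epochs near the series boundaries are scored with the
#' out-of-range window positions padded by zero counts.
#'
#' @param epochs An [epoch_series()].
#' @param config A [ck_config()].
#' @return A [sleep_wake_series()] aligned to `epochs`.
#' @export
score_cole_kripke <- function(epochs, config = ck_config()) {
  stopifnot(inherits(epochs, "epoch_series"), inherits(config, "ck_config"))
  n <- length(epochs)
  if (n == 0L) stop("cannot score an empty series", call. = FALSE)
  a <- pmin(as.numeric(epochs$counts), config$count_cap)
  offsets <- seq_along(config$weights) - config$center
  score <- numeric(n)
  for (k in seq_along(offsets)) {
    off <- offsets[k]
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    score[ok] <- score[ok] + config$weights[k] * a[src[ok]]
  }
  score <- config$scale * score
  sleep_wake_series(epochs$participant_id, epochs$start_time,
                    score < config$threshold)
}
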