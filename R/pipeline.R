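#' Pipeline configuration
#'
#' Assembles a validated configuration for [run_pipeline()]. Exactly one
#' input source must be given (`simulate`, or `epoch_files` + `sleep_log`),
#' and exactly one detection mode (`methods`, named Tudor-Locke parameter
#' sets; or `grid`, a sensitivity-analysis grid).
#'
#' @param out_dir Output directory for run artifacts.
#' @param epoch_files Character vector of epoch CSV paths (one per
#'   participant).
#' @param sleep_log Path to the sleep-log CSV.
#' @param simulate List with elements `spec` (a [cohort_spec()]) and `seed`;
#'   used instead of input files.
#' @param scorer A [ck_config()].
#' @param methods Named list of [tl_params()] sets to run and compare (e.g.
#'   `list(TLD = tl_default(), TLO = tl_chronic_pain())`). Log-defined
#'   periods are always included as method `SL`.
#' @param grid A [grid_spec()] for grid mode; mutually exclusive with
#'   `methods`.
#' @param strategy Missing-data strategy for the comparison tables.
#' @param min_nights Night-sufficiency threshold applied to each participant.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, epoch_files = NULL, sleep_log = NULL,
                            simulate = NULL, scorer = ck_config(),
                            methods = list(TLD = tl_default(),
                                           TLO = tl_chronic_pain()),
                            grid = NULL,
                            strategy = c("complete_case", "zero_impute"),
                            min_nights = 5) {
  strategy <- match.arg(strategy)
  has_files <- !is.null(epoch_files) && !is.null(sleep_log)
  if (is.null(simulate) == !has_files) {
    stop("supply exactly one input source: `simulate`, or `epoch_files` ",
         "with `sleep_log`", call. = FALSE)
  }
  if (!is.null(grid) && !is.null(methods)) {
    stop("`grid` and `methods` modes are mutually exclusive; set the other ",
         "to NULL", call. = FALSE)
  }
  if (is.null(grid) && is.null(methods)) {
    stop("one of `methods` or `grid` is required", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, epoch_files = epoch_files,
         sleep_log = sleep_log, simulate = simulate, scorer = scorer,
         methods = methods, grid = grid, strategy = strategy,
         min_nights = min_nights),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Supported blocks: `out_dir`, `epoch_files`, `sleep_log`,
#' `simulate: {seed, preset | spec fields}`, `scorer: {weights, center,
#' scale, threshold, count_cap}`, `tudor_locke: {<method name>: {bedtime_def,
#' waketime_def, min_period_len, min_nonzero_epochs, max_period_len}}`,
#' `grid: {bedtime_def: [...], ...}`, `strategy`, `min_nights`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scorer <- if (is.null(y$scorer)) ck_config() else do.call(ck_config, y$scorer)
  simulate <- NULL
  if (!is.null(y$simulate)) {
    seed <- y$simulate$seed
    spec <- if (identical(y$simulate$preset, "chronic_pain")) {
      chronic_pain_preset()
    } else {
      do.call(cohort_spec, y$simulate[setdiff(names(y$simulate),
                                              c("seed", "preset"))])
    }
    simulate <- list(spec = spec, seed = seed)
  }
  methods <- NULL
  if (!is.null(y$tudor_locke)) {
    methods <- lapply(y$tudor_locke, function(m) do.call(tl_params, m))
  }
  grid <- if (!is.null(y$grid)) do.call(grid_spec, y$grid) else NULL
  if (!is.null(grid)) methods <- NULL
  pipeline_config(
    out_dir = y$out_dir,
    epoch_files = y$epoch_files, sleep_log = y$sleep_log,
    simulate = simulate, scorer = scorer,
    methods = if (is.null(methods) && is.null(grid)) {
      list(TLD = tl_default(), TLO = tl_chronic_pain())
    } else methods,
    grid = grid,
    strategy = if (is.null(y$strategy)) "complete_case" else y$strategy,
    min_nights = if (is.null(y$min_nights)) 5 else y$min_nights
  )
}

load_datasets <- function(config) {
  if (!is.null(config$simulate)) {
    return(generate_cohort(config$simulate$spec, config$simulate$seed))
  }
  log <- read_sleep_log(config$sleep_log)
  lapply(config$epoch_files, function(f) {
    epochs <- read_epoch_csv(f)
    list(epochs = epochs,
         log = log[log$participant_id == epochs$participant_id, ,
                   drop = FALSE])
  })
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the cohort, checks night sufficiency, scores
#' sleep/wake, and then either (single mode) detects periods under each named
#' Tudor-Locke parameter set, computes per-period and daily measures,
#' per-participant agreement with the sleep log, and the method-comparison
#' tables; or (grid mode) runs the full sensitivity analysis. All numeric
#' outputs are written at full precision; reruns with identical inputs
#' reproduce every output byte for byte. On any stage failure, files already
#' written by the run are removed.
#'
#' @param config A [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return Invisibly, a list of in-memory results and written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    written <<- c(written, path)
    path
  }

  datasets <- withCallingHandlers(
    load_datasets(config),
    error = function(e) stop("[input] ", conditionMessage(e), call. = FALSE)
  )

  eligibility <- purrr::map_dfr(datasets, function(d) {
    rep <- check_night_sufficiency(d$epochs, d$log,
                                   min_nights = config$min_nights)
    tibble::tibble(participant_id = rep$participant_id,
                   n_logged = rep$n_logged,
                   n_eligible_nights = rep$n_eligible_nights,
                   eligible = rep$eligible)
  })
  emit(eligibility, "eligibility.csv")
  keep <- eligibility$eligible
  if (!any(keep)) stop("[eligibility] no eligible participants", call. = FALSE)
  datasets <- datasets[keep]

  if (!is.null(config$grid)) {
    result <- grid_search(datasets, config$grid, config$scorer)
    flat <- dplyr::select(result, -"participant_agreement")
    emit(flat, "grid.csv")
    best <- best_params(result)
    manifest <- write_manifest(config, written)
    ok <- TRUE
    return(invisible(list(grid = result, best_params = best,
                          eligibility = eligibility, files = written,
                          manifest = manifest)))
  }

  scored <- lapply(datasets, function(d) score_cole_kripke(d$epochs,
                                                           config$scorer))
  methods <- config$methods
  all_periods <- list()
  daily_by_method <- list()
  agreement_rows <- list()

  for (m in names(methods)) {
    per_m <- purrr::map_dfr(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      periods <- detect_sleep_periods(scored[[i]], d$epochs, methods[[m]])
      meas <- compute_all_measures(periods, scored[[i]], d$epochs)
      agr <- minute_agreement(periods, periods_from_log(d$log, d$epochs))
      agreement_rows[[paste(m, i)]] <<- dplyr::mutate(agr, method = m)
      dplyr::mutate(meas, method = m)
    })
    all_periods[[m]] <- per_m
    daily_by_method[[m]] <- aggregate_daily(per_m)
  }
  sl_periods <- purrr::map_dfr(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    periods <- periods_from_log(d$log, d$epochs)
    dplyr::mutate(compute_all_measures(periods, scored[[i]], d$epochs),
                  method = "SL")
  })
  daily_by_method$SL <- aggregate_daily(sl_periods)

  period_tbl <- dplyr::bind_rows(c(all_periods, list(SL = sl_periods)))
  emit(dplyr::select(period_tbl, "participant_id", "method", "day", "onset",
                     "end", "source", dplyr::all_of(measure_names())),
       "periods.csv")
  daily_tbl <- purrr::imap_dfr(daily_by_method,
                               function(df, m) dplyr::mutate(df, method = m))
  emit(daily_tbl, "daily_measures.csv")

  agreement <- dplyr::bind_rows(agreement_rows)
  cohort <- agreement |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_agreement = cohort_agreement(dplyr::pick(
      dplyr::everything())), .groups = "drop")
  emit(agreement, "agreement.csv")
  emit(cohort, "cohort_agreement.csv")

  paired <- paired_daily_table(daily_by_method)
  missed <- purrr::map_dfr(names(methods), function(m) {
    r <- missed_night_report(paired, m)
    tibble::tibble(method = m, n_missed_days = r$n_missed_days,
                   pct_missed_days = r$pct_missed_days,
                   n_participants = r$n_participants,
                   pct_participants = r$pct_participants,
                   mean_missed_per_affected = r$mean_missed_per_affected)
  })
  emit(missed, "missed_nights.csv")

  strat <- apply_missing_strategy(paired, config$strategy)
  pairs <- lapply(names(methods), function(m) c(m, "SL"))
  if (length(methods) >= 2) {
    pairs <- c(pairs, utils::combn(names(methods), 2, simplify = FALSE))
  }
  pairs <- pairs[!duplicated(lapply(pairs, sort))]
  ba <- compare_measures_bland_altman(strat, pairs)
  wx <- compare_measures_wilcoxon(strat, pairs)
  emit(ba, "bland_altman.csv")
  emit(wx, "wilcoxon.csv")

  manifest <- write_manifest(config, written)
  ok <- TRUE
  invisible(list(
    eligibility = eligibility, periods = period_tbl, daily = daily_tbl,
    agreement = agreement, cohort_agreement = cohort, paired = paired,
    missed_nights = missed, bland_altman = ba, wilcoxon = wx,
    files = written, manifest = manifest
  ))
}

write_manifest <- function(config, files) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  input_md5 <- NULL
  if (!is.null(config$epoch_files)) {
    paths <- c(config$epoch_files, config$sleep_log)
    input_md5 <- as.list(tools::md5sum(paths))
  }
  manifest <- list(
    package = "actisleep",
    version = as.character(utils::packageVersion("actisleep")),
    config_hash = rlang::hash(cfg),
    input_md5 = input_md5,
    outputs = basename(files)
  )
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
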