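# Pipeline orchestration: run configuration, the minutes -> daily-outcome
# processing chain, and the subcommand-style entry points
# (simulate / process / agree / sweep / correlates / report) that the
# inst/cli/actema script exposes on the shell.

#' Default run configuration
#'
#' All module parameters in one nested list.  The defaults reproduce the
#' primary analysis definition: 24 of 30 MVPA minutes, >60-minute /
#' <10-step non-wear (run-total interpretation), 600 wear minutes for a
#' valid day, sweep over m = 15..30 and the three intensity sets.
#'
#' @return a nested list of configuration keys.
#' @seealso [read_config()] to load and merge a YAML file over these
#'   defaults.
#' @export
default_config <- function() {
  list(
    nonwear = list(min_run_minutes = 61L, max_run_steps = 10L,
                   interpretation = "run_total"),
    valid_day = list(min_wear_minutes = 600L),
    bout = list(window_minutes = 30L, active_minutes = 24L,
                intensity_set = c("moderate", "vigorous")),
    sweep = list(m_min = 15L, m_max = 30L,
                 intensity_sets = list(
                   c("light", "moderate", "vigorous"),
                   c("moderate", "vigorous"),
                   "vigorous")),
    agreement = list(min_days_per_participant = 1L, conf = 0.95,
                     boot_n = 2000L, sweep_boot_n = 500L),
    correlates = list(mode = "significant_only", alpha = 0.05),
    synthetic = unclass(synthetic_config()),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(override[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads a YAML file whose keys mirror [default_config()] and merges it
#' over the defaults (unspecified keys keep their default value).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return the merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) schema_error(sprintf("config file not found: %s", path))
  merge_config(cfg, yaml::read_yaml(path))
}

#' Process minutes and EMA records into daily outcomes
#'
#' The full day-level chain: social-day assembly, non-wear detection,
#' validity flags, exercise classification under the configured bout
#' definition, and pairing with the EMA responses.  Per-stage record
#' counts (minutes read, days built, valid days, included days) are
#' attached as attribute `"stage_counts"` so attrition is auditable.
#'
#' @param minutes minute records (data frame or [read_minutes()] result).
#' @param ema EMA records (data frame or [read_ema()] result).
#' @param config a configuration list from [default_config()] /
#'   [read_config()].
#' @return a `daily_outcomes` data frame (see [pair_days()]) with the
#'   classification columns (`valid`, `wear_minutes`,
#'   `max_window_active`) merged in and `"stage_counts"` attached.
#' @export
process_cohort <- function(minutes, ema, config = default_config()) {
  days <- build_social_days(minutes)
  days <- finalize_days(
    days,
    min_run_minutes = config$nonwear$min_run_minutes,
    max_run_steps = config$nonwear$max_run_steps,
    interpretation = config$nonwear$interpretation,
    min_wear_minutes = config$valid_day$min_wear_minutes
  )
  defn <- bout_definition(
    window_minutes = config$bout$window_minutes,
    active_minutes = config$bout$active_minutes,
    intensity_set = config$bout$intensity_set
  )
  cls <- classify_days(days, defn)
  outcomes <- pair_days(cls, ema)
  extra <- cls[, c("participant_id", "day_date", "wear_minutes", "max_window_active")]
  out <- merge(outcomes, extra, by = c("participant_id", "day_date"), all.x = TRUE)
  out <- out[order(out$participant_id, out$day_date), ]
  rownames(out) <- NULL
  class(out) <- c("daily_outcomes", "data.frame")
  attr(out, "stage_counts") <- list(
    n_minutes = nrow(minutes),
    n_days_built = n_days(days),
    n_days_valid = sum(days$valid),
    n_ema_responses = sum(ema$response %in% c("yes", "no")),
    n_days_included = sum(out$included)
  )
  out
}

#' Pipeline subcommands
#'
#' File-to-file entry points mirroring the `actema` command-line script:
#' `run_simulate()` writes a synthetic cohort, `run_process()` turns
#' minutes + EMA CSVs into the daily-outcome table, `run_agree()` computes
#' the agreement JSON, `run_sweep()` the definition-sweep CSV,
#' `run_correlates()` the correlate regressions, and `run_report()` a
#' human-readable markdown report.  Each command is deterministic given
#' its inputs (and seed) and idempotent.
#'
#' @param config a configuration list ([read_config()]).
#' @param out_dir,out output locations.
#' @param seed optional override of `config$seed`.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
run_simulate <- function(config = default_config(), out_dir, seed = NULL) {
  syn <- config$synthetic
  if (!is.null(seed)) syn$seed <- as.integer(seed)
  cfg <- do.call(synthetic_config, syn)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, out_dir)
}

#' @rdname pipeline-commands
#' @param minutes_path,ema_path,daily_path,agreement_path,covariates_path
#'   input file paths.
#' @export
run_process <- function(minutes_path, ema_path, config = default_config(), out) {
  minutes <- read_minutes(minutes_path)
  ema <- read_ema(ema_path)
  outcomes <- process_cohort(minutes, ema, config)
  write_daily_table(outcomes, out)
  invisible(outcomes)
}

#' @rdname pipeline-commands
#' @export
run_agree <- function(daily_path, config = default_config(), out) {
  outcomes <- read_daily_table(daily_path)
  fit <- agreement_analysis(
    outcomes,
    min_days = config$agreement$min_days_per_participant,
    conf = config$agreement$conf,
    boot_n = config$agreement$boot_n,
    seed = config$seed
  )
  write_agreement_json(fit, out)
  invisible(fit)
}

#' @rdname pipeline-commands
#' @export
run_sweep <- function(minutes_path, ema_path, config = default_config(), out) {
  minutes <- read_minutes(minutes_path)
  ema <- read_ema(ema_path)
  days <- build_social_days(minutes)
  days <- finalize_days(
    days,
    min_run_minutes = config$nonwear$min_run_minutes,
    max_run_steps = config$nonwear$max_run_steps,
    interpretation = config$nonwear$interpretation,
    min_wear_minutes = config$valid_day$min_wear_minutes
  )
  sw <- sweep_definitions(days,
                          m_range = config$sweep$m_min:config$sweep$m_max,
                          intensity_sets = config$sweep$intensity_sets,
                          W = config$bout$window_minutes)
  res <- sweep_agreement(sw, ema,
                         min_days = config$agreement$min_days_per_participant,
                         conf = config$agreement$conf,
                         boot_n = config$agreement$sweep_boot_n,
                         seed = config$seed)
  write_sweep_csv(res, out)
  invisible(res)
}

#' @rdname pipeline-commands
#' @export
run_correlates <- function(agreement_path, covariates_path,
                           config = default_config(), out) {
  agree <- read_agreement_json(agreement_path)
  per <- agree$per_participant
  covariates <- read_covariates(covariates_path)
  # reconstruct outcome-derived predictors from the per-participant tables
  outcomes <- per_participant_outcomes(per)
  design <- build_design(covariates, outcomes)
  kappas <- data.frame(participant_id = per$participant_id, kappa = per$kappa,
                       stringsAsFactors = FALSE)
  uni <- univariate_screen(kappas, design)
  # multivariate fits can be infeasible on small cohorts (more predictors
  # than participants); emit what is estimable and say so
  try_model <- function(...) {
    tryCatch(as.data.frame(multivariate_model(...)),
             actema_contract_error = function(e) {
               message("skipping multivariate model: ", conditionMessage(e))
               NULL
             })
  }
  multi_sig <- try_model(kappas, design, mode = "significant_only",
                         alpha = config$correlates$alpha)
  multi_all <- try_model(kappas, design, mode = "all_covariates")
  res <- rbind(as.data.frame(uni)[, c("predictor", "beta", "se", "p", "n", "model")],
               multi_sig, multi_all)
  class(res) <- c("kappa_correlates", "data.frame")
  write_correlates_csv(res, out)
  invisible(res)
}

# expand per-participant 2x2 counts back into a daily_outcomes frame so
# build_design can compute the percentage predictors
per_participant_outcomes <- function(per) {
  rows <- lapply(seq_len(nrow(per)), function(i) {
    counts <- c(per$a[i], per$b[i], per$c[i], per$d[i])
    ema <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
    accel <- rep(c(TRUE, FALSE, TRUE, FALSE), counts)
    if (!length(ema)) return(NULL)
    data.frame(participant_id = per$participant_id[i],
               day_date = as.Date("2000-01-01") + seq_along(ema) - 1L,
               accel_exercise = accel, ema_exercise = ema, included = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("daily_outcomes", "data.frame")
  out
}

#' @rdname pipeline-commands
#' @param daily_path path to the daily-outcome CSV (from `run_process`).
#' @param sweep_path,correlates_path optional paths; sections are skipped
#'   when absent.
#' @export
run_report <- function(daily_path, agreement_path, sweep_path = NULL,
                       correlates_path = NULL, config = default_config(),
                       out) {
  daily <- read_daily_table(daily_path)
  agree <- read_agreement_json(agreement_path)
  lines <- c("# Day-level agreement report", "")

  n_days_total <- nrow(daily)
  ema_comp <- 100 * mean(!is.na(daily$ema_exercise))
  wear_comp <- 100 * mean(!is.na(daily$accel_exercise))
  lines <- c(lines, "## Compliance", "",
             sprintf("- person-days observed: %d", n_days_total),
             sprintf("- EMA response compliance: %.1f%%", ema_comp),
             sprintf("- valid accelerometer wear: %.1f%%", wear_comp),
             sprintf("- person-days with both measures: %d", sum(daily$included)),
             "")

  inc <- daily[daily$included, ]
  per_pct <- function(col) {
    v <- vapply(split(inc[[col]], inc$participant_id), mean, numeric(1)) * 100
    c(mean = mean(v), sd = sd(v))
  }
  pe <- per_pct("ema_exercise")
  pa <- per_pct("accel_exercise")
  lines <- c(lines, "## Exercise days", "",
             sprintf("- %% of days self-reported exercise: %.1f +/- %.1f (participant mean +/- SD); pooled %.1f%%",
                     pe["mean"], pe["sd"], 100 * mean(inc$ema_exercise)),
             sprintf("- %% of days accelerometer-measured exercise: %.1f +/- %.1f (participant mean +/- SD); pooled %.1f%%",
                     pa["mean"], pa["sd"], 100 * mean(inc$accel_exercise)),
             "")

  s <- agree$summary
  lines <- c(lines, "## Agreement (Cohen's kappa)", "",
             sprintf("- mean kappa: %.2f (SD %.2f), range [%.2f, %.2f]",
                     s$mean, s$sd, s$min, s$max),
             sprintf("- median kappa: %.2f", s$median),
             sprintf("- pooled kappa: %.2f +/- %.2f (SE) over %d person-days",
                     agree$pooled$kappa, agree$pooled$se, agree$pooled$n),
             sprintf("- participants: %d (%d undefined kappa excluded)",
                     s$n_participants, s$n_undefined),
             "")

  if (!is.null(sweep_path) && file.exists(sweep_path)) {
    sw <- read_sweep_csv(sweep_path)
    lines <- c(lines, "## Definition sweep", "",
               "| intensity set | m | mean kappa | median kappa | pooled kappa |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %.3f | %.3f | %.3f |",
                       sw$intensity_set, sw$m, sw$mean_kappa,
                       sw$median_kappa, sw$pooled_kappa),
               "")
  }
  if (!is.null(correlates_path) && file.exists(correlates_path)) {
    cr <- read_correlates_csv(correlates_path)
    lines <- c(lines, "## Correlates of agreement", "",
               "| predictor | beta | SE | p | n | model |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %.3g | %d | %s |",
                       cr$predictor, cr$beta, cr$se, cr$p, cr$n, cr$model),
               "")
  }
  writeLines(lines, out)
  invisible(out)
}
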