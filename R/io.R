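# CSV/JSON interfaces of the pipeline.  Readers validate schemas and
# resolve duplicates deterministically; writers round-trip with their
# readers.  data.table::fread/fwrite do the heavy lifting (minute files
# can run to tens of millions of rows).

read_csv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) schema_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, colClasses = "character",
                          na.strings = NULL, data.table = FALSE)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    schema_error(sprintf("%s: missing required column(s): %s",
                         basename(path), paste(missing_cols, collapse = ", ")))
  }
  dt
}

# data row i lives on file line i + 1 (header)
row_error <- function(path, rows, what) {
  validation_error(sprintf("%s: %s on line %s", basename(path), what,
                           paste(utils::head(rows + 1L, 5L), collapse = ", ")))
}

#' Read a minute-level accelerometer CSV
#'
#' Expects the normalized minute export schema
#' `participant_id,timestamp,steps,intensity` with ISO 8601 local
#' timestamps (`YYYY-MM-DDTHH:MM`), non-negative integer steps and
#' intensity codes 0--3 (sedentary, light, moderate, vigorous).  Records
#' are sorted by (participant, timestamp); duplicate minutes keep the
#' first occurrence in file order and are counted.  The attached
#' `"parse_report"` lists rows read, duplicates dropped, and in-series
#' minute gaps; missing minutes are not imputed here.
#'
#' @param path CSV file path.
#' @return a `minute_data` data frame: `participant_id`, `timestamp`
#'   (`POSIXct`), `steps`, `intensity`, with attribute `"parse_report"`.
#' @export
read_minutes <- function(path) {
  dt <- read_csv_checked(path, c("participant_id", "timestamp", "steps", "intensity"))
  n0 <- nrow(dt)
  ts <- parse_minute_timestamp(dt$timestamp)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) row_error(path, bad_ts, "unparseable timestamp")
  steps <- suppressWarnings(as.numeric(dt$steps))
  bad_steps <- which(is.na(steps) | steps < 0 | steps != floor(steps))
  if (length(bad_steps)) {
    row_error(path, bad_steps, "steps must be a non-negative integer")
  }
  intensity <- suppressWarnings(as.numeric(dt$intensity))
  bad_int <- which(!intensity %in% 0:3)
  if (length(bad_int)) {
    row_error(path, bad_int, "intensity must be one of 0, 1, 2, 3")
  }
  dup <- duplicated(data.frame(p = dt$participant_id, t = as.numeric(ts)))
  out <- data.frame(
    participant_id = dt$participant_id[!dup],
    timestamp = ts[!dup],
    steps = as.integer(steps[!dup]),
    intensity = as.integer(intensity[!dup]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$timestamp), ]
  rownames(out) <- NULL
  # gaps: missing minutes between consecutive records of one participant
  dmin <- diff(as.numeric(out$timestamp) %/% 60)
  same <- out$participant_id[-1] == out$participant_id[-nrow(out)]
  n_gaps <- if (nrow(out) > 1L) sum(pmax(dmin[same] - 1, 0)) else 0
  attr(out, "parse_report") <- list(
    n_rows = n0, n_duplicates = sum(dup), n_gaps = as.numeric(n_gaps)
  )
  class(out) <- c("minute_data", "data.frame")
  out
}

#' Write a minute-level CSV
#'
#' @param minutes a data frame as returned by [read_minutes()] or
#'   `generate_cohort()$minutes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_minutes <- function(minutes, path) {
  out <- data.frame(
    participant_id = minutes$participant_id,
    timestamp = format(parse_minute_timestamp(minutes$timestamp),
                       "%Y-%m-%dT%H:%M", tz = "UTC"),
    steps = minutes$steps,
    intensity = minutes$intensity
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a daily EMA CSV
#'
#' Expects `participant_id,report_date,response[,completed_at]`.
#' Responses `1/yes` and `0/no` (case-insensitive) are normalized to
#' `"yes"`/`"no"`; empty responses become `"missing"`.  When a
#' participant-day appears more than once, the record with the latest
#' `completed_at` wins; with tied or absent timestamps the first file row
#' wins.  Conflicts are counted in the `"parse_report"` attribute.
#'
#' @param path CSV file path.
#' @return an `ema_data` data frame: `participant_id`, `report_date`
#'   (`Date`), `response`, `completed_at` (`POSIXct`, `NA` if absent).
#' @export
read_ema <- function(path) {
  dt <- read_csv_checked(path, c("participant_id", "report_date", "response"))
  n0 <- nrow(dt)
  dates <- as.Date(dt$report_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) row_error(path, bad, "unparseable report_date")
  resp_raw <- tolower(trimws(dt$response))
  response <- ifelse(resp_raw %in% c("1", "yes"), "yes",
              ifelse(resp_raw %in% c("0", "no"), "no",
              ifelse(resp_raw == "" | resp_raw == "na", "missing", NA)))
  bad_resp <- which(is.na(response))
  if (length(bad_resp)) {
    row_error(path, bad_resp, "response must be one of 0, 1, yes, no, or empty")
  }
  completed <- if ("completed_at" %in% names(dt)) {
    parse_minute_timestamp(ifelse(trimws(dt$completed_at) == "", NA, dt$completed_at))
  } else rep(as.POSIXct(NA), n0)

  out <- data.frame(
    participant_id = dt$participant_id,
    report_date = dates,
    response = response,
    completed_at = completed,
    stringsAsFactors = FALSE
  )
  # duplicate resolution: latest completed_at wins; ties/NA -> first row
  key <- paste(out$participant_id, out$report_date)
  comp_num <- ifelse(is.na(as.numeric(out$completed_at)), -Inf,
                     as.numeric(out$completed_at))
  ord <- order(key, -comp_num, seq_len(nrow(out)))
  out <- out[ord, ]
  dup <- duplicated(paste(out$participant_id, out$report_date))
  n_conflicts <- sum(dup)
  out <- out[!dup, ]
  out <- out[order(out$participant_id, out$report_date), ]
  rownames(out) <- NULL
  attr(out, "parse_report") <- list(n_rows = n0, n_conflicts = n_conflicts)
  class(out) <- c("ema_data", "data.frame")
  out
}

#' Write a daily EMA CSV
#'
#' @param ema a data frame with `participant_id`, `report_date`,
#'   `response`, optional `completed_at`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ema <- function(ema, path) {
  out <- data.frame(
    participant_id = ema$participant_id,
    report_date = format(as_date_utc(ema$report_date), "%Y-%m-%d"),
    response = ema$response,
    completed_at = if ("completed_at" %in% names(ema)) {
      ifelse(is.na(ema$completed_at), "",
             format(parse_minute_timestamp(ema$completed_at),
                    "%Y-%m-%dT%H:%M", tz = "UTC"))
    } else ""
  )
  data.table::fwrite(out, path)
  invisible(path)
}

COVARIATE_NUMERIC <- c("age", "bmi", "black", "hispanic", "grad_degree",
                       "partner", "caregiver", "mean_stress", "tech_use")

#' Read a participant covariate CSV
#'
#' Expects `participant_id,age,sex,bmi,black,hispanic,grad_degree,partner,
#' caregiver,mean_stress,tech_use`.  `sex` must be `female`/`male` or
#' `1`/`0` (1 = female); binary columns must be 0/1; empty optional fields
#' become `NA` (never zero), and downstream regressions drop such
#' participants listwise for models that use the column.
#'
#' @param path CSV file path.
#' @return a data frame of per-participant covariates with a `female`
#'   0/1 indicator added.
#' @export
read_covariates <- function(path) {
  dt <- read_csv_checked(path, c("participant_id", "age", "sex"))
  sex_raw <- tolower(trimws(dt$sex))
  bad_sex <- which(!sex_raw %in% c("female", "male", "0", "1"))
  if (length(bad_sex)) {
    row_error(path, bad_sex, "sex must be female, male, 0 or 1")
  }
  out <- data.frame(participant_id = dt$participant_id,
                    stringsAsFactors = FALSE)
  out$sex <- ifelse(sex_raw %in% c("female", "1"), "female", "male")
  out$female <- as.numeric(out$sex == "female")
  for (col in c("age", COVARIATE_NUMERIC)) {
    if (!col %in% names(dt)) {
      out[[col]] <- NA_real_
      next
    }
    raw <- trimws(dt[[col]])
    vals <- suppressWarnings(as.numeric(ifelse(raw == "", NA, raw)))
    bad <- which(raw != "" & is.na(vals))
    if (length(bad)) row_error(path, bad, sprintf("non-numeric %s", col))
    out[[col]] <- vals
  }
  bad_age <- which(!is.na(out$age) & out$age <= 0)
  if (length(bad_age)) row_error(path, bad_age, "age must be positive")
  bad_bmi <- which(!is.na(out$bmi) & out$bmi <= 0)
  if (length(bad_bmi)) row_error(path, bad_bmi, "bmi must be positive")
  for (col in c("black", "hispanic", "grad_degree", "partner", "caregiver", "tech_use")) {
    bad <- which(!is.na(out[[col]]) & !out[[col]] %in% c(0, 1))
    if (length(bad)) row_error(path, bad, sprintf("%s must be 0 or 1", col))
  }
  out
}

#' Write a participant covariate CSV
#'
#' @param covariates data frame with the covariate schema columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  cols <- c("participant_id", "age", "sex", "bmi", "black", "hispanic",
            "grad_degree", "partner", "caregiver", "mean_stress", "tech_use")
  out <- covariates[, intersect(cols, names(covariates))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write / read the daily-outcome table
#'
#' One row per (participant, social day); `accel_exercise` and
#' `ema_exercise` are `1`/`0` with empty cells for absent values; the
#' pair round-trips (`read(write(x))` equals `x`).
#'
#' @param outcomes a `daily_outcomes` data frame from [pair_days()].
#' @param path CSV path.
#' @return `write_daily_table()`: `path` invisibly; `read_daily_table()`:
#'   the `daily_outcomes` data frame.
#' @export
write_daily_table <- function(outcomes, path) {
  enc <- function(x) ifelse(is.na(x), "", as.character(as.integer(x)))
  out <- data.frame(
    participant_id = outcomes$participant_id,
    day_date = format(as_date_utc(outcomes$day_date), "%Y-%m-%d"),
    accel_exercise = enc(outcomes$accel_exercise),
    ema_exercise = enc(outcomes$ema_exercise),
    included = as.integer(outcomes$included)
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_daily_table
#' @export
read_daily_table <- function(path) {
  dt <- read_csv_checked(path, c("participant_id", "day_date",
                                 "accel_exercise", "ema_exercise", "included"))
  dec <- function(x) ifelse(trimws(x) == "", NA, x == "1")
  out <- data.frame(
    participant_id = dt$participant_id,
    day_date = as.Date(dt$day_date),
    accel_exercise = dec(dt$accel_exercise),
    ema_exercise = dec(dt$ema_exercise),
    included = dt$included == "1",
    stringsAsFactors = FALSE
  )
  class(out) <- c("daily_outcomes", "data.frame")
  out
}

#' Write / read the agreement JSON
#'
#' Serializes an [agreement_analysis()] fit as
#' `{per_participant: [...], pooled: {...}, summary: {...}}`.
#'
#' @param fit an `ema_agreement` object.
#' @param path JSON path.
#' @return `write_agreement_json()`: `path` invisibly;
#'   `read_agreement_json()`: the parsed list.
#' @export
write_agreement_json <- function(fit, path) {
  stopifnot(inherits(fit, "ema_agreement"))
  payload <- list(
    per_participant = fit$per_participant[
      , c("participant_id", "kappa", "n", "a", "b", "c", "d")],
    pooled = list(kappa = fit$pooled$kappa, se = fit$pooled$se,
                  n = fit$pooled$n),
    summary = list(mean = fit$summary$mean, sd = fit$summary$sd,
                   median = fit$summary$median,
                   min = fit$summary$min, max = fit$summary$max,
                   ci_mean = fit$summary$ci_mean,
                   ci_median = fit$summary$ci_median,
                   n_participants = fit$summary$n_participants,
                   n_undefined = fit$summary$n_undefined)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_agreement_json
#' @export
read_agreement_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read the sweep CSV
#'
#' Schema: `intensity_set,m,mean_kappa,sd_kappa,median_kappa,ci_low,
#' ci_high,pooled_kappa,pooled_se,n_participants,n_days`.
#'
#' @param sweep an `agreement_sweep` data frame from [sweep_agreement()].
#' @param path CSV path.
#' @return `write_sweep_csv()`: `path` invisibly; `read_sweep_csv()`: the
#'   `agreement_sweep` data frame.
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- c("intensity_set", "m", "mean_kappa", "sd_kappa", "median_kappa",
            "ci_low", "ci_high", "pooled_kappa", "pooled_se",
            "n_participants", "n_days")
  data.table::fwrite(as.data.frame(sweep)[, cols], path)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  class(dt) <- c("agreement_sweep", "data.frame")
  dt
}

#' Write / read the correlates CSV
#'
#' Schema: `predictor,beta,se,p,n,model` (plus the supplementary `p_bh`
#' column when present).
#'
#' @param correlates a `kappa_correlates` data frame.
#' @param path CSV path.
#' @return `write_correlates_csv()`: `path` invisibly;
#'   `read_correlates_csv()`: the data frame.
#' @export
write_correlates_csv <- function(correlates, path) {
  data.table::fwrite(as.data.frame(correlates), path)
  invisible(path)
}

#' @rdname write_correlates_csv
#' @export
read_correlates_csv <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  class(dt) <- c("kappa_correlates", "data.frame")
  dt
}

#' Write a synthetic cohort's CSV files
#'
#' Emits `minutes.csv`, `ema.csv`, `covariates.csv` and
#' `ground_truth.csv` (schema `participant_id,day_date,true_exercise`)
#' into `dir`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    minutes = file.path(dir, "minutes.csv"),
    ema = file.path(dir, "ema.csv"),
    covariates = file.path(dir, "covariates.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  write_minutes(cohort$minutes, paths[["minutes"]])
  write_ema(cohort$ema, paths[["ema"]])
  write_covariates(cohort$covariates, paths[["covariates"]])
  truth <- data.frame(
    participant_id = cohort$truth$participant_id,
    day_date = format(as_date_utc(cohort$truth$day_date), "%Y-%m-%d"),
    true_exercise = as.integer(cohort$truth$true_exercise)
  )
  data.table::fwrite(truth, paths[["ground_truth"]])
  invisible(paths)
}

#' @rdname write_cohort
#' @param path ground-truth CSV path.
#' @export
read_ground_truth <- function(path) {
  dt <- read_csv_checked(path, c("participant_id", "day_date", "true_exercise"))
  data.frame(
    participant_id = dt$participant_id,
    day_date = as.Date(dt$day_date),
    true_exercise = dt$true_exercise == "1",
    stringsAsFactors = FALSE
  )
}
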