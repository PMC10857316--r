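# Social-day assembly, non-wear detection and wear-time validity.
#
# A "social day" runs from 03:00 to 02:59 the next civil morning, so that
# late-evening activity and the end-of-day report fall on the same analysis
# day.  All times are naive local civil time; internally they are stored as
# POSIXct in UTC purely as a timezone-free container.

#' Map a timestamp to its social day
#'
#' The social day is the 24 h span from 03:00 to 02:59 the next morning and
#' is labelled by the civil date on which it starts: times at or after 03:00
#' belong to that date, times before 03:00 belong to the previous date.
#'
#' @param timestamp a `POSIXct` vector (treated as naive civil time), or a
#'   character vector in `"YYYY-MM-DDTHH:MM"` / `"YYYY-MM-DD HH:MM"` form.
#' @return a `Date` vector: the social-day label of each timestamp.
#' @examples
#' assign_social_day(c("2020-05-01T03:00", "2020-05-02T02:59", "2020-05-01T00:00"))
#' @export
assign_social_day <- function(timestamp) {
  ts <- parse_minute_timestamp(timestamp)
  mins <- as.numeric(ts) %/% 60
  as.Date(floor((mins - DAY_START_MINUTE) / MINUTES_PER_DAY),
          origin = "1970-01-01")
}

# slot 0 = 03:00, slot 1439 = 02:59 next morning
social_slot <- function(timestamp) {
  ts <- parse_minute_timestamp(timestamp)
  as.integer((as.numeric(ts) %/% 60 - DAY_START_MINUTE) %% MINUTES_PER_DAY)
}

parse_minute_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M")
  # allow a seconds field too
  retry <- is.na(out) & !is.na(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  out
}

#' Assemble minute records into social days
#'
#' Maps every minute record to a (participant, social day, slot) cell and
#' returns one 1440-slot day per distinct social day touched by the data.
#' Slots with no data row get `steps = 0`, `intensity = sedentary` and
#' `observed = FALSE`; every input minute lands in exactly one slot.  If two
#' records map to the same slot (e.g. clock anomalies) the first one wins.
#'
#' @param minutes a data frame with columns `participant_id`, `timestamp`
#'   (`POSIXct` or ISO 8601 character), `steps`, `intensity`, as returned by
#'   [read_minutes()] or [generate_cohort()].
#' @return a `social_days` object: a column-per-day container with fields
#'   `participant_id`, `day_date`, and 1440-row matrices `steps`,
#'   `intensity`, `observed` (plus `wear`, `wear_minutes`, `valid` once
#'   [finalize_days()] has run).
#' @seealso [detect_nonwear()], [finalize_days()], [classify_days()]
#' @export
build_social_days <- function(minutes) {
  required <- c("participant_id", "timestamp", "steps", "intensity")
  missing_cols <- setdiff(required, names(minutes))
  if (length(missing_cols)) {
    contract_error(sprintf("minutes input lacks column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  ts <- parse_minute_timestamp(minutes$timestamp)
  mins <- as.numeric(ts) %/% 60
  slot <- as.integer((mins - DAY_START_MINUTE) %% MINUTES_PER_DAY)
  day_index <- floor((mins - DAY_START_MINUTE) / MINUTES_PER_DAY)

  pid <- as.character(minutes$participant_id)
  pid_levels <- sort(unique(pid))
  pcode <- match(pid, pid_levels)

  offset <- min(day_index)
  key <- (pcode - 1) * 2^21 + (day_index - offset)
  ukey <- sort(unique(key))
  col <- match(key, ukey)
  n_days <- length(ukey)

  steps <- matrix(0L, nrow = MINUTES_PER_DAY, ncol = n_days)
  intensity <- matrix(0L, nrow = MINUTES_PER_DAY, ncol = n_days)
  observed <- matrix(FALSE, nrow = MINUTES_PER_DAY, ncol = n_days)

  idx <- (col - 1L) * MINUTES_PER_DAY + slot + 1L
  keep <- !duplicated(idx)
  steps[idx[keep]] <- as.integer(minutes$steps[keep])
  intensity[idx[keep]] <- as.integer(minutes$intensity[keep])
  observed[idx[keep]] <- TRUE

  structure(list(
    participant_id = pid_levels[ukey %/% 2^21 + 1],
    day_date = as.Date(ukey %% 2^21 + offset, origin = "1970-01-01"),
    steps = steps,
    intensity = intensity,
    observed = observed,
    wear = NULL,
    wear_minutes = NULL,
    valid = NULL
  ), class = "social_days")
}

#' @export
print.social_days <- function(x, ...) {
  cat(sprintf("<social_days> %d day(s), %d participant(s)\n",
              n_days(x), length(unique(x$participant_id))))
  if (!is.null(x$valid)) {
    cat(sprintf("  valid days (>= wear threshold): %d (%.1f%%)\n",
                sum(x$valid), 100 * mean(x$valid)))
  } else {
    cat("  non-wear not yet detected; run finalize_days()\n")
  }
  invisible(x)
}

n_days <- function(days) length(days$day_date)

#' Extract one social day
#'
#' @param days a `social_days` object.
#' @param i day index (column).
#' @return a list with the per-day fields (`participant_id`, `day_date`,
#'   `steps`, `intensity`, `observed`, and `wear`/`wear_minutes`/`valid`
#'   when available).
#' @export
social_day <- function(days, i) {
  stopifnot(inherits(days, "social_days"), i >= 1L, i <= n_days(days))
  out <- list(
    participant_id = days$participant_id[i],
    day_date = days$day_date[i],
    steps = days$steps[, i],
    intensity = days$intensity[, i],
    observed = days$observed[, i]
  )
  if (!is.null(days$wear)) {
    out$wear <- days$wear[, i]
    out$wear_minutes <- days$wear_minutes[i]
    out$valid <- days$valid[i]
  }
  out
}

#' Detect non-wear minutes in one social day
#'
#' Non-wear is a run of more than 60 consecutive low-step minutes ("more
#' than 60" is strict: a 60-minute run is wear).  Unobserved slots count as
#' zero-step minutes and are eligible to join runs.  Two interpretations of
#' the step criterion are available:
#'
#' * `"run_total"` (default): a minute is non-wear when it lies inside
#'   *some* stretch of at least `min_run_minutes` consecutive minutes whose
#'   total step count is below `max_run_steps` (the step criterion attaches
#'   to the whole span).  A single minute carrying `max_run_steps` or more
#'   steps can never belong to such a stretch, so it splits runs.
#' * `"per_minute"`: maximal runs of minutes that are each individually
#'   below `max_run_steps` (or unobserved), at least `min_run_minutes`
#'   long.
#'
#' Runs never bridge the 02:59 -> 03:00 day boundary because detection is
#' per-day.
#'
#' @param steps,observed integer/logical vectors of length 1440.
#' @param min_run_minutes minimum qualifying run length (default 61,
#'   i.e. strictly more than 60 minutes).
#' @param max_run_steps step threshold (default 10, "fewer than 10 steps").
#' @param interpretation `"run_total"` (default) or `"per_minute"`; see
#'   Details.
#' @return logical `wear[1440]`: `TRUE` where the minute counts as wear.
#' @export
detect_nonwear <- function(steps, observed,
                           min_run_minutes = 61L,
                           max_run_steps = 10L,
                           interpretation = c("run_total", "per_minute")) {
  interpretation <- match.arg(interpretation)
  if (length(steps) != MINUTES_PER_DAY || length(observed) != MINUTES_PER_DAY) {
    contract_error("steps and observed must have length 1440")
  }
  steps <- as.numeric(steps)
  steps[!observed] <- 0
  n <- MINUTES_PER_DAY
  wear <- rep(TRUE, n)
  if (interpretation == "per_minute") {
    candidate <- !observed | steps < max_run_steps
    r <- rle(as.logical(candidate))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run_minutes)) {
      wear[starts[j]:ends[j]] <- FALSE
    }
    return(wear)
  }
  # run_total: mark every minute covered by some span of length
  # >= min_run_minutes whose total steps < max_run_steps.  With the
  # cumulative sum S, the furthest right end reachable from left end l is
  # the largest r with S[r] - S[l-1] < max_run_steps; totals are
  # non-negative so S is non-decreasing and the reach is a findInterval.
  S <- cumsum(steps)
  reach <- findInterval(c(0, S[-n]) + max_run_steps - 1e-9, S)
  qual <- which(reach - seq_len(n) + 1L >= min_run_minutes)
  if (length(qual)) {
    cover <- tabulate(qual, n + 1L) - tabulate(reach[qual] + 1L, n + 1L)
    wear[cumsum(cover[seq_len(n)]) > 0L] <- FALSE
  }
  wear
}

#' Compute wear masks, wear minutes and validity for all days
#'
#' Runs [detect_nonwear()] on every day, counts wear minutes, and flags a
#' day valid when it has at least `min_wear_minutes` of wear (default
#' 600, i.e. at least 10 h).  Only valid days enter agreement analyses.
#'
#' @param days a `social_days` object from [build_social_days()].
#' @param min_run_minutes,max_run_steps,interpretation passed to
#'   [detect_nonwear()].
#' @param min_wear_minutes validity threshold in minutes (default 600).
#' @return `days` with `wear`, `wear_minutes` and `valid` filled in.
#' @export
finalize_days <- function(days,
                          min_run_minutes = 61L,
                          max_run_steps = 10L,
                          interpretation = c("run_total", "per_minute"),
                          min_wear_minutes = 600L) {
  stopifnot(inherits(days, "social_days"))
  interpretation <- match.arg(interpretation)
  n <- n_days(days)
  wear <- matrix(TRUE, nrow = MINUTES_PER_DAY, ncol = n)
  for (i in seq_len(n)) {
    wear[, i] <- detect_nonwear(days$steps[, i], days$observed[, i],
                                min_run_minutes = min_run_minutes,
                                max_run_steps = max_run_steps,
                                interpretation = interpretation)
  }
  days$wear <- wear
  days$wear_minutes <- as.integer(colSums(wear))
  days$valid <- days$wear_minutes >= min_wear_minutes
  days
}
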