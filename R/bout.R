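# Sliding-window exercise-day classification and the definition sweep.
#
# A day is an exercise day when some consecutive W-minute window contains at
# least m active minutes (primary definition: 24 of 30 MVPA minutes, which
# tolerates up to 6 below-threshold minutes inside the bout).  Windows are
# confined to the 1440-slot social day and non-wear minutes are gated out
# before counting.

#' Bout definition
#'
#' @param window_minutes window length W in minutes (default 30).
#' @param active_minutes required active minutes m within the window
#'   (default 24).
#' @param intensity_set intensity levels that count as active; subset of
#'   `c("light", "moderate", "vigorous")` (default moderate+vigorous, i.e.
#'   MVPA).  Sedentary minutes are never active.
#' @return a `bout_definition` object.
#' @export
bout_definition <- function(window_minutes = 30L,
                            active_minutes = 24L,
                            intensity_set = c("moderate", "vigorous")) {
  W <- as.integer(window_minutes)
  m <- as.integer(active_minutes)
  if (is.na(W) || is.na(m) || m < 1L || m > W || W > MINUTES_PER_DAY) {
    contract_error("bout definition requires 1 <= active_minutes <= window_minutes <= 1440")
  }
  codes <- normalize_intensity_set(intensity_set)
  structure(list(window_minutes = W, active_minutes = m,
                 intensity_set = codes,
                 label = intensity_set_label(codes)),
            class = "bout_definition")
}

#' @export
print.bout_definition <- function(x, ...) {
  cat(sprintf("<bout_definition> %d of %d min, intensity: %s\n",
              x$active_minutes, x$window_minutes, x$label))
  invisible(x)
}

#' Active-minute indicator for one day
#'
#' A minute is active when it is a wear minute and its intensity belongs to
#' the intensity set.  Minutes inside non-wear runs never count, whatever
#' intensity the device recorded for them.
#'
#' @param intensity integer vector of length 1440 (codes 0--3).
#' @param wear logical vector of length 1440.
#' @param intensity_set as in [bout_definition()].
#' @return logical `active[1440]`.
#' @export
active_indicator <- function(intensity, wear,
                             intensity_set = c("moderate", "vigorous")) {
  if (length(intensity) != MINUTES_PER_DAY || length(wear) != MINUTES_PER_DAY) {
    contract_error("intensity and wear must have length 1440")
  }
  codes <- normalize_intensity_set(intensity_set)
  wear & (intensity %in% codes)
}

#' Maximum active-minute count over all W-minute windows
#'
#' Running-sum sliding window, O(n) per day; windows never cross the day
#' boundary.  Equivalent to brute-force enumeration of all `n - W + 1`
#' windows.
#'
#' @param active logical/0-1 vector (length 1440 for a social day).
#' @param W window length, `W <= length(active)`.
#' @return integer: the maximum number of active minutes in any window.
#' @export
max_window_active <- function(active, W = 30L) {
  n <- length(active)
  W <- as.integer(W)
  if (is.na(W) || W < 1L || W > n) {
    contract_error("window length W must satisfy 1 <= W <= length(active)")
  }
  cs <- cumsum(as.integer(active))
  as.integer(max(cs[W:n] - c(0L, cs[seq_len(n - W)])))
}

#' Classify social days as exercise / non-exercise
#'
#' Applies a [bout_definition()] to every day: computes each day's maximum
#' windowed active-minute count and thresholds it at `active_minutes`.
#' Classification is computed for every day (downstream analyses filter on
#' `valid`).
#'
#' @param days a finalized `social_days` object (see [finalize_days()]).
#' @param defn a [bout_definition()].
#' @return a data frame with one row per day: `participant_id`, `day_date`,
#'   `valid`, `wear_minutes`, `max_window_active`, `exercise`.
#' @export
classify_days <- function(days, defn = bout_definition()) {
  stopifnot(inherits(days, "social_days"), inherits(defn, "bout_definition"))
  if (is.null(days$wear)) {
    contract_error("days must be finalized (finalize_days) before classification")
  }
  n <- n_days(days)
  mwa <- integer(n)
  for (i in seq_len(n)) {
    act <- days$wear[, i] & (days$intensity[, i] %in% defn$intensity_set)
    mwa[i] <- max_window_active(act, defn$window_minutes)
  }
  data.frame(
    participant_id = days$participant_id,
    day_date = days$day_date,
    valid = days$valid,
    wear_minutes = days$wear_minutes,
    max_window_active = mwa,
    exercise = mwa >= defn$active_minutes,
    stringsAsFactors = FALSE
  )
}

#' Sweep bout definitions over duration and intensity criteria
#'
#' For each intensity set the windowed maximum is computed once per day and
#' then thresholded at every duration `m` in `m_range` (single pass over the
#' minutes, 16 thresholds by default).  The result feeds
#' [sweep_agreement()].
#'
#' @param days a finalized `social_days` object.
#' @param m_range integer vector of duration thresholds (default `15:30`).
#' @param intensity_sets list of intensity sets (default: all intensities,
#'   MVPA, vigorous only).
#' @param W window length in minutes (default 30).
#' @return a `bout_sweep` object: per-day metadata plus a
#'   days x sets matrix of windowed maxima; `as.data.frame()` expands it to
#'   one row per (set, m, day) classification.
#' @export
sweep_definitions <- function(days,
                              m_range = 15:30,
                              intensity_sets = list(
                                c("light", "moderate", "vigorous"),
                                c("moderate", "vigorous"),
                                "vigorous"
                              ),
                              W = 30L) {
  stopifnot(inherits(days, "social_days"))
  if (length(m_range) == 0L) contract_error("m_range must be non-empty")
  m_range <- sort(as.integer(m_range))
  if (any(m_range < 1L) || any(m_range > W)) {
    contract_error("every m in m_range must satisfy 1 <= m <= W")
  }
  if (is.null(days$wear)) {
    contract_error("days must be finalized (finalize_days) before sweeping")
  }
  labels <- vapply(intensity_sets, intensity_set_label, character(1))
  n <- n_days(days)
  mwa <- matrix(0L, nrow = n, ncol = length(intensity_sets),
                dimnames = list(NULL, labels))
  for (s in seq_along(intensity_sets)) {
    codes <- normalize_intensity_set(intensity_sets[[s]])
    for (i in seq_len(n)) {
      act <- days$wear[, i] & (days$intensity[, i] %in% codes)
      mwa[i, s] <- max_window_active(act, W)
    }
  }
  structure(list(
    participant_id = days$participant_id,
    day_date = days$day_date,
    valid = days$valid,
    max_window_active = mwa,
    m_range = m_range,
    window_minutes = as.integer(W),
    set_labels = labels
  ), class = "bout_sweep")
}

#' @export
print.bout_sweep <- function(x, ...) {
  cat(sprintf("<bout_sweep> %d day(s) x %d intensity set(s) x m in %d..%d (W = %d)\n",
              length(x$day_date), length(x$set_labels),
              min(x$m_range), max(x$m_range), x$window_minutes))
  invisible(x)
}

#' @export
#' @method as.data.frame bout_sweep
as.data.frame.bout_sweep <- function(x, ...) {
  grid <- expand.grid(m = x$m_range, intensity_set = x$set_labels,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    s <- grid$intensity_set[k]
    data.frame(
      intensity_set = s,
      m = grid$m[k],
      participant_id = x$participant_id,
      day_date = x$day_date,
      valid = x$valid,
      max_window_active = x$max_window_active[, s],
      exercise = x$max_window_active[, s] >= grid$m[k],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
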