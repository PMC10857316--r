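# Shared fixtures: hand-rolled days, brute-force oracles, tiny CSV writers.

full_wear_day <- function(fill_steps = 20L, fill_intensity = 0L) {
  list(steps = rep(as.integer(fill_steps), 1440L),
       observed = rep(TRUE, 1440L),
       intensity = rep(as.integer(fill_intensity), 1440L))
}

# quadratic oracle: enumerate every W-window and count active minutes
brute_force_mwa <- function(active, W) {
  n <- length(active)
  starts <- seq_len(n - W + 1L)
  max(vapply(starts, function(s) sum(active[s:(s + W - 1L)]), numeric(1)))
}

# random day with clumped activity so windows are non-trivial
random_activity_day <- function() {
  intensity <- rep(0L, 1440L)
  n_bouts <- sample(0:4, 1)
  for (b in seq_len(n_bouts)) {
    len <- sample(5:60, 1)
    start <- sample(1:(1440 - len), 1)
    intensity[start:(start + len - 1L)] <-
      sample(0:3, len, replace = TRUE, prob = c(0.2, 0.2, 0.35, 0.25))
  }
  # scattered single active minutes
  intensity[sample(1440, 30)] <- sample(1:3, 30, replace = TRUE)
  wear <- rep(TRUE, 1440L)
  if (runif(1) < 0.5) {
    len <- sample(61:300, 1)
    start <- sample(1:(1440 - len), 1)
    wear[start:(start + len - 1L)] <- FALSE
  }
  list(intensity = intensity, wear = wear)
}

write_lines_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# random daily_outcomes frame for property tests
random_outcomes <- function(n, n_participants = 4) {
  data.frame(
    participant_id = sample(sprintf("P%d", seq_len(n_participants)), n, replace = TRUE),
    day_date = as.Date("2020-01-01") + sample(0:400, n, replace = TRUE),
    accel_exercise = sample(c(TRUE, FALSE, NA), n, replace = TRUE, prob = c(.4, .4, .2)),
    ema_exercise = sample(c(TRUE, FALSE, NA), n, replace = TRUE, prob = c(.4, .4, .2)),
    stringsAsFactors = FALSE
  ) |> (\(d) {
    d <- d[!duplicated(d[c("participant_id", "day_date")]), ]
    d$included <- !is.na(d$accel_exercise) & !is.na(d$ema_exercise)
    class(d) <- c("daily_outcomes", "data.frame")
    d
  })()
}
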