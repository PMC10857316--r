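# Synthetic cohort generator with known ground truth, plus the analytic
# kappa oracle and a fast day-level generator for agreement-layer tests.
#
# The full generator works mechanistically at the minute level: a
# background of sedentary/light minutes over a daily wear span, one
# inserted MVPA bout on true exercise days, optional extra non-wear runs,
# and an EMA response drawn with configurable sensitivity / specificity
# against the latent truth.  The day-level fast path draws (accel, EMA)
# pairs directly from the two-noisy-raters model the analytic oracle
# describes.

#' Synthetic cohort configuration
#'
#' Defaults describe the emulated study: 79 participants followed for 365
#' days; per-day true exercise probability with cohort mean 0.32 and
#' Beta-distributed between-person heterogeneity; MVPA bouts of 25--60
#' minutes with up to 6 embedded rest minutes; EMA response probability
#' (compliance) 0.64 and day-validity (wear) probability 0.68.  EMA error
#' rates default to se = 0.631, sp = 0.745, the values at which, for a
#' near-truth accelerometer and prevalence 0.32, the model reproduces an
#' EMA yes-rate of 37.5% and a pooled kappa of 0.36.
#'
#' @param n_participants,n_days cohort size (defaults 79 x 365).
#' @param start_date first social day (civil date).
#' @param exercise_prevalence cohort-mean per-day probability of true
#'   exercise (default 0.32).
#' @param prevalence_concentration Beta concentration (alpha + beta) of
#'   the per-participant prevalence distribution; default 7 gives a
#'   between-person SD of about 0.165.
#' @param bout_minutes length-2 range of MVPA minutes per inserted bout
#'   (default `c(25, 60)`).
#' @param bout_rest_max maximum rest minutes embedded in a bout (default
#'   6); rest minutes are placed after the first 24 MVPA minutes so a
#'   genuine bout always satisfies the primary 24-of-30 rule.
#' @param ema_sensitivity,ema_specificity P(EMA yes | exercise) and
#'   P(EMA no | no exercise).
#' @param ema_compliance probability an EMA response is present (0.64).
#' @param wear_compliance probability a day is worn long enough to be
#'   valid (0.68).
#' @param nonwear_runs_per_day Poisson mean of extra non-wear runs
#'   inserted into worn days (default 0.3).
#' @param nonwear_run_minutes length-2 range of inserted run lengths
#'   (default `c(61, 180)`).
#' @param incidental_mvpa_rate per-minute probability of background
#'   (non-bout) MVPA, default 0 (used to stress-test false positives).
#' @param light_rate per-minute probability of a light-intensity
#'   background minute (default 0.18).
#' @param seed integer RNG seed; a fixed seed makes the generated cohort
#'   byte-identical across runs.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 79L,
                             n_days = 365L,
                             start_date = "2020-01-01",
                             exercise_prevalence = 0.32,
                             prevalence_concentration = 7,
                             bout_minutes = c(25L, 60L),
                             bout_rest_max = 6L,
                             ema_sensitivity = 0.631,
                             ema_specificity = 0.745,
                             ema_compliance = 0.64,
                             wear_compliance = 0.68,
                             nonwear_runs_per_day = 0.3,
                             nonwear_run_minutes = c(61L, 180L),
                             incidental_mvpa_rate = 0,
                             light_rate = 0.18,
                             seed = 1L) {
  probs <- c(exercise_prevalence, ema_sensitivity, ema_specificity,
             ema_compliance, wear_compliance, incidental_mvpa_rate,
             light_rate)
  if (any(probs < 0 | probs > 1)) {
    contract_error("all probabilities must lie in [0, 1]")
  }
  if (n_participants < 1L || n_days < 1L) {
    contract_error("n_participants and n_days must be >= 1")
  }
  bout_minutes <- as.integer(bout_minutes)
  if (length(bout_minutes) != 2L || bout_minutes[1] > bout_minutes[2] ||
      bout_minutes[1] < 1L) {
    contract_error("bout_minutes must be an increasing range of positive minutes")
  }
  if (bout_minutes[2] + bout_rest_max > MINUTES_PER_DAY) {
    contract_error("bout longer than a day cannot be placed")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    start_date = as_date_utc(start_date),
    exercise_prevalence = exercise_prevalence,
    prevalence_concentration = prevalence_concentration,
    bout_minutes = bout_minutes,
    bout_rest_max = as.integer(bout_rest_max),
    ema_sensitivity = ema_sensitivity,
    ema_specificity = ema_specificity,
    ema_compliance = ema_compliance,
    wear_compliance = wear_compliance,
    nonwear_runs_per_day = nonwear_runs_per_day,
    nonwear_run_minutes = as.integer(nonwear_run_minutes),
    incidental_mvpa_rate = incidental_mvpa_rate,
    light_rate = light_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_config> %d participants x %d days (seed %d)\n",
    "  prevalence %.3f (concentration %.1f), bouts %d-%d MVPA min (<= %d rest)\n",
    "  EMA se/sp %.3f/%.3f, compliance EMA %.2f / wear %.2f\n"),
    x$n_participants, x$n_days, x$seed,
    x$exercise_prevalence, x$prevalence_concentration,
    x$bout_minutes[1], x$bout_minutes[2], x$bout_rest_max,
    x$ema_sensitivity, x$ema_specificity,
    x$ema_compliance, x$wear_compliance))
  invisible(x)
}

# step-count Poisson means by context
STEP_LAMBDA <- c(sedentary = 6, light = 45, mvpa = 110, rest = 5)

#' Generate a synthetic cohort with known ground truth
#'
#' For each participant-day: the true exercise state is Bernoulli with the
#' participant's latent prevalence; worn days get a continuous daytime
#' wear span of background sedentary/light minutes; true exercise days
#' (when worn) get one MVPA bout placed uniformly within the span, with
#' its first 24 minutes contiguous MVPA and any embedded rest minutes
#' after them; optional extra non-wear runs (zero-step stretches) are
#' carved out of the span without ever pushing a worn day below the 600
#' wear-minute validity threshold.  The EMA response is drawn from the
#' truth with the configured sensitivity/specificity and masked to missing
#' with probability `1 - ema_compliance`.  Covariates are drawn to match
#' the emulated cohort's margins (57% female, age 31.9 +/- 9.5,
#' BMI 26.4 +/- 5.3, ...), independently of the agreement process.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_cohort` list: `minutes` (participant_id,
#'   timestamp, steps, intensity), `ema` (participant_id, report_date,
#'   response, completed_at), `covariates`, `truth` (participant_id,
#'   day_date, true_exercise, plus each participant's latent prevalence in
#'   `attr(truth, "prevalence")`), and `config`.
#' @seealso [write_cohort()] to emit the CSV interfaces,
#'   [day_level_generator()] for the fast day-level path.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    mu <- cfg$exercise_prevalence
    conc <- cfg$prevalence_concentration
    pi_i <- if (conc > 0) {
      rbeta(cfg$n_participants, mu * conc, (1 - mu) * conc)
    } else rep(mu, cfg$n_participants)
    pids <- sprintf("P%03d", seq_len(cfg$n_participants))
    dates <- cfg$start_date + seq_len(cfg$n_days) - 1L

    covariates <- data.frame(
      participant_id = pids,
      age = round(pmax(18, rnorm(cfg$n_participants, 31.9, 9.5)), 1),
      sex = ifelse(runif(cfg$n_participants) < 0.57, "female", "male"),
      bmi = round(pmax(16, rnorm(cfg$n_participants, 26.4, 5.3)), 1),
      black = as.integer(runif(cfg$n_participants) < 0.139),
      hispanic = as.integer(runif(cfg$n_participants) < 0.278),
      grad_degree = as.integer(runif(cfg$n_participants) < 0.405),
      partner = as.integer(runif(cfg$n_participants) < 0.405),
      caregiver = as.integer(runif(cfg$n_participants) < 0.494),
      mean_stress = round(pmin(40, pmax(0, rnorm(cfg$n_participants, 22.6, 6))), 1),
      tech_use = as.integer(runif(cfg$n_participants) < 0.494),
      stringsAsFactors = FALSE
    )

    minute_parts <- vector("list", cfg$n_participants)
    ema_parts <- vector("list", cfg$n_participants)
    truth_parts <- vector("list", cfg$n_participants)

    for (p in seq_len(cfg$n_participants)) {
      nd <- cfg$n_days
      true_ex <- runif(nd) < pi_i[p]
      worn <- runif(nd) < cfg$wear_compliance

      # daytime wear span in social-slot coordinates (slot 0 = 03:00):
      # worn days start 06:00-08:00 and carry 700-1020 observed minutes,
      # unworn days at most 500 (never enough for validity)
      span_start <- sample(180:300, nd, replace = TRUE)
      span_len <- ifelse(worn,
                         sample(700:1020, nd, replace = TRUE),
                         sample(0:500, nd, replace = TRUE))

      slot <- sequence(span_len, from = span_start)
      day_rep <- rep.int(seq_len(nd), span_len)
      n_min <- length(slot)

      u <- runif(n_min)
      intensity <- ifelse(u < cfg$light_rate, 1L, 0L)
      if (cfg$incidental_mvpa_rate > 0) {
        intensity[runif(n_min) < cfg$incidental_mvpa_rate] <- 2L
      }
      lambda <- ifelse(intensity == 0L, STEP_LAMBDA[["sedentary"]],
                ifelse(intensity == 1L, STEP_LAMBDA[["light"]],
                       STEP_LAMBDA[["mvpa"]]))
      steps <- rpois(n_min, lambda)

      offsets <- c(0L, cumsum(span_len))  # block start of each day - 1
      bout_bounds <- matrix(NA_integer_, nrow = nd, ncol = 2L)

      # one MVPA bout per true exercise day that is worn
      for (d in which(true_ex & worn & span_len > 0)) {
        mvpa_len <- sample(cfg$bout_minutes[1]:cfg$bout_minutes[2], 1L)
        n_rest <- if (cfg$bout_rest_max > 0L) sample(0:cfg$bout_rest_max, 1L) else 0L
        total <- mvpa_len + n_rest
        if (total > span_len[d]) {
          total <- span_len[d]
          n_rest <- 0L
          mvpa_len <- total
        }
        start_in_span <- sample.int(span_len[d] - total + 1L, 1L)
        pos <- offsets[d] + start_in_span - 1L + seq_len(total)
        is_rest <- rep(FALSE, total)
        if (n_rest > 0L && total > 24L) {
          # rest only after the first 24 MVPA minutes: the leading
          # 30-minute window always holds >= 24 active minutes
          tail_pos <- 25:total
          is_rest[sample(tail_pos, min(n_rest, length(tail_pos)))] <- TRUE
        }
        vig <- runif(total) < 0.3
        intensity[pos] <- ifelse(is_rest, 0L, ifelse(vig, 3L, 2L))
        steps[pos] <- rpois(total, ifelse(is_rest, STEP_LAMBDA[["rest"]],
                                          STEP_LAMBDA[["mvpa"]]))
        # remember placement so the non-wear inserter below avoids the bout
        bout_bounds[d, ] <- c(start_in_span, start_in_span + total - 1L)
      }

      # extra non-wear runs inside worn spans (zero-step sedentary
      # stretches), capped so a worn day keeps >= 620 wear minutes
      if (cfg$nonwear_runs_per_day > 0) {
        n_runs <- rpois(nd, cfg$nonwear_runs_per_day)
        for (d in which(worn & n_runs > 0)) {
          budget <- span_len[d] - 620L
          for (r in seq_len(n_runs[d])) {
            len <- sample(cfg$nonwear_run_minutes[1]:cfg$nonwear_run_minutes[2], 1L)
            if (len > budget) break
            ok_start <- FALSE
            for (try in 1:5) {
              s0 <- sample.int(span_len[d] - len + 1L, 1L)
              if (is.na(bout_bounds[d, 1]) ||
                  s0 + len - 1L < bout_bounds[d, 1] || s0 > bout_bounds[d, 2]) {
                ok_start <- TRUE
                break
              }
            }
            if (!ok_start) next
            pos <- offsets[d] + s0 - 1L + seq_len(len)
            steps[pos] <- 0L
            intensity[pos] <- 0L
            budget <- budget - len
          }
        }
      }

      minute_parts[[p]] <- data.frame(
        participant_id = rep.int(pids[p], n_min),
        timestamp = as.POSIXct(as.numeric(as.POSIXct(dates[day_rep], tz = "UTC")) +
                                 (DAY_START_MINUTE + slot) * 60,
                               origin = "1970-01-01", tz = "UTC"),
        steps = steps,
        intensity = intensity,
        stringsAsFactors = FALSE
      )

      # EMA: drawn from truth for every day, masked by compliance
      says_yes <- ifelse(true_ex,
                         runif(nd) < cfg$ema_sensitivity,
                         runif(nd) < 1 - cfg$ema_specificity)
      responded <- runif(nd) < cfg$ema_compliance
      comp_min <- sample(1230:1380, nd, replace = TRUE)  # 20:30-23:00 civil
      ema_parts[[p]] <- data.frame(
        participant_id = rep.int(pids[p], sum(responded)),
        report_date = dates[responded],
        response = ifelse(says_yes[responded], "yes", "no"),
        completed_at = as.POSIXct(as.numeric(as.POSIXct(dates[responded], tz = "UTC")) +
                                    comp_min[responded] * 60,
                                  origin = "1970-01-01", tz = "UTC"),
        stringsAsFactors = FALSE
      )

      truth_parts[[p]] <- data.frame(
        participant_id = rep.int(pids[p], nd),
        day_date = dates,
        true_exercise = true_ex,
        stringsAsFactors = FALSE
      )
    }

    truth <- do.call(rbind, truth_parts)
    rownames(truth) <- NULL
    attr(truth, "prevalence") <- setNames(pi_i, pids)
    structure(list(
      minutes = data.table::rbindlist(minute_parts),
      ema = do.call(rbind, ema_parts),
      covariates = covariates,
      truth = truth,
      config = cfg
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, %s minute rows, %d EMA responses\n",
              x$config$n_participants,
              format(nrow(x$minutes), big.mark = ","), nrow(x$ema)))
  print(x$config)
  invisible(x)
}

#' Analytic kappa for the two-noisy-raters model
#'
#' Models the accelerometer and the EMA item as conditionally independent
#' binary raters of a latent exercise state with prevalence `prevalence`:
#' the joint cell probabilities are
#' \eqn{P(A=a, E=e) = \pi f_A(a|1) f_E(e|1) + (1-\pi) f_A(a|0) f_E(e|0)},
#' from which the population kappa follows via its observed- and
#' chance-agreement probabilities.  This closed form is the oracle against
#' which empirical kappas from [day_level_generator()] converge.
#'
#' @param prevalence latent exercise prevalence \eqn{\pi}.
#' @param accel_sensitivity,accel_specificity accelerometer error model.
#' @param ema_sensitivity,ema_specificity EMA error model.
#' @return a `kappa_result` (with the joint 2x2 attached as attribute
#'   `"joint"`); undefined when a marginal is degenerate.
#' @examples
#' analytic_kappa(0.3, 0.9, 0.95, 0.7, 0.8)  # ~0.404
#' @export
analytic_kappa <- function(prevalence,
                           accel_sensitivity, accel_specificity,
                           ema_sensitivity, ema_specificity) {
  probs <- c(prevalence, accel_sensitivity, accel_specificity,
             ema_sensitivity, ema_specificity)
  if (any(probs < 0 | probs > 1)) {
    contract_error("all arguments must be probabilities in [0, 1]")
  }
  pi <- prevalence
  fa <- function(a, s) if (s == 1) {
    if (a == 1) accel_sensitivity else 1 - accel_sensitivity
  } else {
    if (a == 1) 1 - accel_specificity else accel_specificity
  }
  fe <- function(e, s) if (s == 1) {
    if (e == 1) ema_sensitivity else 1 - ema_sensitivity
  } else {
    if (e == 1) 1 - ema_specificity else ema_specificity
  }
  joint <- matrix(0, 2, 2,
                  dimnames = list(ema = c("yes", "no"), accel = c("yes", "no")))
  for (a in 0:1) for (e in 0:1) {
    pr <- pi * fa(a, 1) * fe(e, 1) + (1 - pi) * fa(a, 0) * fe(e, 0)
    joint[2 - e, 2 - a] <- pr
  }
  p_o <- joint[1, 1] + joint[2, 2]
  row1 <- sum(joint[1, ]); col1 <- sum(joint[, 1])
  p_e <- row1 * col1 + (1 - row1) * (1 - col1)
  out <- if (1 - p_e < 1e-12) {
    kappa_undefined(NA_integer_, "degenerate marginals")
  } else {
    structure(list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e,
                   se = NA_real_, n = NA_integer_, undefined = FALSE,
                   reason = NA_character_),
              class = "kappa_result")
  }
  attr(out, "joint") <- joint
  out
}

#' Fast day-level outcome generator
#'
#' Draws i.i.d. (accelerometer, EMA) day outcomes directly from the
#' two-noisy-raters joint distribution of [analytic_kappa()], bypassing
#' minute simulation.  Used for convergence tests of empirical versus
#' analytic kappa.
#'
#' @inheritParams analytic_kappa
#' @param n_days number of person-days to draw.
#' @param seed optional RNG seed.
#' @param participant_id id attached to the outcomes (default `"SIM"`).
#' @return a `daily_outcomes` data frame with all days included.
#' @export
day_level_generator <- function(prevalence,
                                accel_sensitivity, accel_specificity,
                                ema_sensitivity, ema_specificity,
                                n_days, seed = NULL,
                                participant_id = "SIM") {
  if (n_days < 1L) contract_error("n_days must be >= 1")
  with_seed(seed, {
    truth <- runif(n_days) < prevalence
    accel <- ifelse(truth, runif(n_days) < accel_sensitivity,
                    runif(n_days) < 1 - accel_specificity)
    ema <- ifelse(truth, runif(n_days) < ema_sensitivity,
                  runif(n_days) < 1 - ema_specificity)
    out <- data.frame(
      participant_id = rep.int(participant_id, n_days),
      day_date = as.Date("2020-01-01") + seq_len(n_days) - 1L,
      accel_exercise = as.logical(accel),
      ema_exercise = as.logical(ema),
      included = TRUE,
      stringsAsFactors = FALSE
    )
    class(out) <- c("daily_outcomes", "data.frame")
    attr(out, "truth") <- truth
    out
  })
}
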