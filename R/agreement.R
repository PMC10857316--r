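# Day-level agreement: pairing, 2x2 tables, Cohen's kappa (per participant
# and pooled with an asymptotic SE), cross-participant summaries and the
# definition-sweep agreement curves.

#' Pair accelerometer day classifications with EMA responses
#'
#' Produces one row per (participant, social day) present in either source.
#' A day is `included` in agreement analyses only when the accelerometer day
#' is valid (>= 10 h wear) *and* the EMA response is yes/no; the
#' accelerometer classification is reported as `NA` on invalid days and the
#' EMA response as `NA` when missing.
#'
#' @param classifications data frame from [classify_days()] (columns
#'   `participant_id`, `day_date`, `valid`, `exercise`).
#' @param ema data frame of EMA records (columns `participant_id`,
#'   `report_date`, `response` in `"yes"/"no"/"missing"`), as from
#'   [read_ema()] or [generate_cohort()].
#' @return a `daily_outcomes` data frame: `participant_id`, `day_date`,
#'   `accel_exercise`, `ema_exercise` (logical, `NA` when absent),
#'   `included`.
#' @export
pair_days <- function(classifications, ema) {
  need <- c("participant_id", "day_date", "valid", "exercise")
  if (length(setdiff(need, names(classifications)))) {
    contract_error("classifications must carry participant_id, day_date, valid, exercise")
  }
  cls <- classifications[, need]
  ema2 <- data.frame(
    participant_id = as.character(ema$participant_id),
    day_date = as_date_utc(ema$report_date),
    response = as.character(ema$response),
    stringsAsFactors = FALSE
  )
  merged <- merge(cls, ema2,
                  by = c("participant_id", "day_date"), all = TRUE)
  accel <- ifelse(!is.na(merged$valid) & merged$valid, merged$exercise, NA)
  ema_ex <- ifelse(is.na(merged$response) | merged$response == "missing",
                   NA, merged$response == "yes")
  out <- data.frame(
    participant_id = merged$participant_id,
    day_date = merged$day_date,
    accel_exercise = as.logical(accel),
    ema_exercise = as.logical(ema_ex),
    included = !is.na(accel) & !is.na(ema_ex),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$day_date), ]
  rownames(out) <- NULL
  class(out) <- c("daily_outcomes", "data.frame")
  out
}

#' 2x2 contingency table of included days
#'
#' Counts over included days only, in the orientation
#' `a` = EMA yes & accel yes, `b` = EMA yes & accel no,
#' `c` = EMA no & accel yes, `d` = EMA no & accel no.
#'
#' @param outcomes a `daily_outcomes` data frame (typically one
#'   participant's rows).
#' @return a named numeric vector `c(a=, b=, c=, d=)` of class
#'   `contingency_2x2`.
#' @export
contingency <- function(outcomes) {
  inc <- outcomes[outcomes$included, , drop = FALSE]
  e <- inc$ema_exercise
  a <- inc$accel_exercise
  structure(c(a = sum(e & a), b = sum(e & !a),
              c = sum(!e & a), d = sum(!e & !a)),
            class = "contingency_2x2")
}

as_contingency <- function(t) {
  if (inherits(t, "contingency_2x2")) return(unclass(t))
  if (is.matrix(t) && all(dim(t) == 2L)) {
    return(c(a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2]))
  }
  if (is.numeric(t) && length(t) == 4L) {
    return(setNames(as.numeric(t), c("a", "b", "c", "d")))
  }
  contract_error("expected a contingency_2x2, a 2x2 matrix, or 4 counts (a,b,c,d)")
}

kappa_undefined <- function(n, reason) {
  structure(list(kappa = NA_real_, p_o = NA_real_, p_e = NA_real_,
                 se = NA_real_, n = n, undefined = TRUE, reason = reason),
            class = "kappa_result")
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_o = (a+d)/n} and \eqn{p_e = rs + (1-r)(1-s)} for marginals
#' \eqn{r = (a+b)/n}, \eqn{s = (a+c)/n}.  When either measure is constant
#' over the days (a degenerate marginal) kappa is undefined and flagged
#' rather than imputed.
#'
#' @param t a `contingency_2x2` from [contingency()], a 2x2 matrix
#'   (rows = EMA yes/no, columns = accelerometer yes/no), or counts
#'   `c(a, b, c, d)`.
#' @return a `kappa_result`: `kappa`, `p_o`, `p_e`, `se` (filled by
#'   [pooled_kappa()] only), `n`, `undefined`, `reason`.
#' @examples
#' cohen_kappa(c(50, 10, 10, 30))  # kappa = 0.58333...
#' @export
cohen_kappa <- function(t) {
  t <- as_contingency(t)
  if (any(t < 0)) contract_error("contingency counts must be non-negative")
  n <- sum(t)
  if (n == 0) return(kappa_undefined(0, "no included days"))
  p_o <- (t[["a"]] + t[["d"]]) / n
  r <- (t[["a"]] + t[["b"]]) / n
  s <- (t[["a"]] + t[["c"]]) / n
  p_e <- r * s + (1 - r) * (1 - s)
  # a measure that never varies cannot support chance-corrected agreement:
  # flagged undefined rather than imputed (0 would bias summaries)
  if (r %in% c(0, 1) || s %in% c(0, 1)) {
    out <- kappa_undefined(n, "degenerate marginals (a measure is constant)")
    out$p_o <- p_o
    out$p_e <- p_e
    return(out)
  }
  structure(list(kappa = (p_o - p_e) / (1 - p_e),
                 p_o = p_o, p_e = p_e, se = NA_real_, n = n,
                 undefined = FALSE, reason = NA_character_),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, digits = 3, ...) {
  if (x$undefined) {
    cat(sprintf("<kappa_result> undefined (%s), n = %d\n", x$reason, x$n))
  } else {
    se_txt <- if (is.na(x$se)) "" else sprintf(" +/- %.*f (SE)", digits, x$se)
    cat(sprintf("<kappa_result> kappa = %.*f%s  (p_o = %.*f, p_e = %.*f, n = %d)\n",
                digits, x$kappa, se_txt, digits, x$p_o, digits, x$p_e, x$n))
  }
  invisible(x)
}

# Asymptotic variance of kappa for a 2x2 table (large-sample delta-method
# form of Fleiss, Cohen & Everitt): with joint proportions p_ij, row
# marginals p_i., column marginals p_.j,
#   Var = [ sum_i p_ii ((1-p_e) - (p_.i + p_i.)(1-p_o))^2
#           + (1-p_o)^2 sum_{i!=j} p_ij (p_.i + p_j.)^2
#           - (p_o p_e - 2 p_e + p_o)^2 ] / (N (1-p_e)^4)
kappa_asymptotic_se <- function(t) {
  t <- as_contingency(t)
  n <- sum(t)
  p11 <- t[["a"]] / n; p12 <- t[["b"]] / n
  p21 <- t[["c"]] / n; p22 <- t[["d"]] / n
  r1 <- p11 + p12; r2 <- p21 + p22     # row marginals p_i. (EMA)
  c1 <- p11 + p21; c2 <- p12 + p22     # column marginals p_.j (accel)
  p_o <- p11 + p22
  p_e <- r1 * c1 + r2 * c2
  if (1 - p_e < 1e-12) return(NA_real_)
  term_diag <- p11 * ((1 - p_e) - (c1 + r1) * (1 - p_o))^2 +
    p22 * ((1 - p_e) - (c2 + r2) * (1 - p_o))^2
  term_off <- (1 - p_o)^2 * (p12 * (c1 + r2)^2 + p21 * (c2 + r1)^2)
  term_const <- (p_o * p_e - 2 * p_e + p_o)^2
  v <- (term_diag + term_off - term_const) / (n * (1 - p_e)^4)
  sqrt(max(v, 0))
}

#' Pooled kappa across participants
#'
#' Sums the per-participant 2x2 tables element-wise and computes Cohen's
#' kappa on the pooled table, with the asymptotic standard error of the
#' Fleiss--Cohen--Everitt large-sample variance.  A nonparametric bootstrap
#' SE over the pooled person-days is available as a cross-check.
#'
#' @param tables a list of contingency tables (any form accepted by
#'   [cohen_kappa()]), or a single table.
#' @param se_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap resamples when `se_method = "bootstrap"`.
#' @param seed optional seed for the bootstrap.
#' @return a `kappa_result` with `se` set; the pooled table is attached as
#'   attribute `"table"`.
#' @export
pooled_kappa <- function(tables, se_method = c("asymptotic", "bootstrap"),
                         boot_n = 2000L, seed = NULL) {
  se_method <- match.arg(se_method)
  if (!is.list(tables)) tables <- list(tables)
  if (length(tables) == 0L) return(kappa_undefined(0, "no tables"))
  pooled <- Reduce(`+`, lapply(tables, as_contingency))
  out <- cohen_kappa(pooled)
  if (!out$undefined) {
    out$se <- if (se_method == "asymptotic") {
      kappa_asymptotic_se(pooled)
    } else {
      kappa_bootstrap_se(pooled, boot_n = boot_n, seed = seed)
    }
  }
  attr(out, "table") <- pooled
  out
}

#' Bootstrap standard error of kappa for a 2x2 table
#'
#' Multinomial resampling of the n person-days in the table; the SE is the
#' standard deviation of kappa over resamples (undefined resamples are
#' dropped).
#'
#' @inheritParams cohen_kappa
#' @param boot_n number of resamples (default 2000).
#' @param seed optional RNG seed.
#' @return numeric SE.
#' @export
kappa_bootstrap_se <- function(t, boot_n = 2000L, seed = NULL) {
  t <- as_contingency(t)
  n <- sum(t)
  if (n == 0) return(NA_real_)
  with_seed(seed, {
    draws <- stats::rmultinom(boot_n, size = n, prob = t / n)
    a <- draws[1, ]; b <- draws[2, ]; cc <- draws[3, ]; d <- draws[4, ]
    p_o <- (a + d) / n
    r <- (a + b) / n
    s <- (a + cc) / n
    p_e <- r * s + (1 - r) * (1 - s)
    k <- (p_o - p_e) / (1 - p_e)
    k[1 - p_e < 1e-12] <- NA
    sd(k, na.rm = TRUE)
  })
}

#' Per-participant kappa table
#'
#' @param outcomes a `daily_outcomes` data frame for the whole cohort.
#' @param min_days minimum number of included days a participant needs to
#'   get a kappa (default 1; no floor).
#' @return a data frame with one row per participant meeting the floor:
#'   `participant_id`, `kappa`, `n`, `a`, `b`, `c`, `d`, `undefined`,
#'   `reason`.
#' @export
per_participant_kappas <- function(outcomes, min_days = 1L) {
  split_idx <- split(seq_len(nrow(outcomes)), outcomes$participant_id)
  rows <- lapply(names(split_idx), function(p) {
    t <- contingency(outcomes[split_idx[[p]], , drop = FALSE])
    if (sum(t) < min_days) return(NULL)
    k <- cohen_kappa(t)
    data.frame(participant_id = p, kappa = k$kappa, n = k$n,
               a = unname(t["a"]), b = unname(t["b"]),
               c = unname(t["c"]), d = unname(t["d"]),
               undefined = k$undefined, reason = k$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), kappa = numeric(),
                      n = integer(), a = numeric(), b = numeric(),
                      c = numeric(), d = numeric(), undefined = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarise per-participant kappas
#'
#' Moments are taken over defined kappas only; participants whose kappa is
#' undefined (a constant measure) are excluded and counted in
#' `n_undefined`.  The mean gets a t-interval; the median gets a seeded
#' percentile-bootstrap interval.
#'
#' @param kappas numeric vector of kappas (may contain `NA` = undefined),
#'   or the data frame from [per_participant_kappas()].
#' @param conf confidence level (default 0.95).
#' @param boot_n bootstrap resamples for the median CI (default 2000).
#' @param seed optional RNG seed for the bootstrap.
#' @return a `kappa_summary` list: `mean`, `sd`, `median`, `min`, `max`,
#'   `ci_mean`, `ci_median`, `n_participants`, `n_undefined`.
#' @export
summarize_kappas <- function(kappas, conf = 0.95, boot_n = 2000L, seed = NULL) {
  if (is.data.frame(kappas)) kappas <- kappas$kappa
  defined <- kappas[!is.na(kappas)]
  n_undef <- sum(is.na(kappas))
  n <- length(defined)
  if (n == 0L) {
    return(structure(list(mean = NA_real_, sd = NA_real_, median = NA_real_,
                          min = NA_real_, max = NA_real_,
                          ci_mean = c(NA_real_, NA_real_),
                          ci_median = c(NA_real_, NA_real_),
                          n_participants = 0L, n_undefined = n_undef,
                          empty = TRUE),
                     class = "kappa_summary"))
  }
  m <- mean(defined)
  s <- if (n > 1L) sd(defined) else NA_real_
  alpha <- 1 - conf
  ci_mean <- if (n > 1L) {
    m + c(-1, 1) * qt(1 - alpha / 2, df = n - 1L) * s / sqrt(n)
  } else c(NA_real_, NA_real_)
  ci_median <- with_seed(seed, {
    meds <- vapply(seq_len(boot_n), function(i) {
      median(sample(defined, n, replace = TRUE))
    }, numeric(1))
    unname(quantile(meds, c(alpha / 2, 1 - alpha / 2), type = 7))
  })
  structure(list(mean = m, sd = s, median = median(defined),
                 min = min(defined), max = max(defined),
                 ci_mean = ci_mean, ci_median = ci_median,
                 n_participants = n, n_undefined = n_undef,
                 empty = FALSE),
            class = "kappa_summary")
}

#' @export
print.kappa_summary <- function(x, digits = 3, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("<kappa_summary> empty (no defined kappas; %d undefined)\n",
                x$n_undefined))
    return(invisible(x))
  }
  cat(sprintf("<kappa_summary> n = %d participants (%d undefined excluded)\n",
              x$n_participants, x$n_undefined))
  cat(sprintf("  mean %.*f (SD %.*f), 95%% CI [%.*f, %.*f]\n",
              digits, x$mean, digits, x$sd,
              digits, x$ci_mean[1], digits, x$ci_mean[2]))
  cat(sprintf("  median %.*f, bootstrap 95%% CI [%.*f, %.*f], range [%.*f, %.*f]\n",
              digits, x$median, digits, x$ci_median[1], digits, x$ci_median[2],
              digits, x$min, digits, x$max))
  invisible(x)
}

#' Fit the day-level agreement analysis
#'
#' The central analysis: per-participant Cohen's kappa over included days,
#' the pooled kappa (+/- asymptotic SE) over all person-days, and the
#' cross-participant summary.
#'
#' @param outcomes a `daily_outcomes` data frame from [pair_days()].
#' @param min_days per-participant floor on included days (default 1).
#' @param conf,boot_n,seed passed to [summarize_kappas()].
#' @return an `ema_agreement` object with elements `per_participant`
#'   (data frame), `pooled` (`kappa_result`), `summary` (`kappa_summary`),
#'   `n_days` (included person-days).
#' @examples
#' out <- day_level_generator(0.3, 0.9, 0.95, 0.7, 0.8, n_days = 500, seed = 1)
#' fit <- agreement_analysis(out)
#' fit
#' @export
agreement_analysis <- function(outcomes, min_days = 1L, conf = 0.95,
                               boot_n = 2000L, seed = NULL) {
  per <- per_participant_kappas(outcomes, min_days = min_days)
  tables <- lapply(seq_len(nrow(per)), function(i) {
    c(a = per$a[i], b = per$b[i], c = per$c[i], d = per$d[i])
  })
  pooled <- pooled_kappa(tables)
  summ <- summarize_kappas(per$kappa, conf = conf, boot_n = boot_n, seed = seed)
  structure(list(per_participant = per, pooled = pooled, summary = summ,
                 n_days = sum(per$n), min_days = min_days),
            class = "ema_agreement")
}

#' @export
print.ema_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("<ema_agreement> %d participants, %d included person-days\n",
              nrow(x$per_participant), x$n_days))
  if (!x$pooled$undefined) {
    cat(sprintf("  pooled kappa: %.*f +/- %.*f (SE)\n",
                digits, x$pooled$kappa, digits, x$pooled$se))
  } else {
    cat(sprintf("  pooled kappa: undefined (%s)\n", x$pooled$reason))
  }
  if (!isTRUE(x$summary$empty)) {
    cat(sprintf("  per-participant: mean %.*f (SD %.*f), median %.*f, range [%.*f, %.*f]\n",
                digits, x$summary$mean, digits, x$summary$sd,
                digits, x$summary$median,
                digits, x$summary$min, digits, x$summary$max))
  }
  if (x$summary$n_undefined > 0L) {
    cat(sprintf("  %d participant(s) with undefined kappa excluded from moments\n",
                x$summary$n_undefined))
  }
  invisible(x)
}

#' @export
summary.ema_agreement <- function(object, ...) {
  print(object, ...)
  print(object$summary)
  invisible(object)
}

#' @export
coef.ema_agreement <- function(object, ...) {
  setNames(object$per_participant$kappa, object$per_participant$participant_id)
}

#' Agreement across the bout-definition sweep
#'
#' For every (intensity set, duration m) cell of a [sweep_definitions()]
#' result, pairs days with the EMA responses (pairing, and hence the
#' included-day count, does not depend on m), computes per-participant and
#' pooled kappas, and summarises them.  This is the data behind the
#' mean/median-kappa-versus-duration curves.
#'
#' @param sweep a `bout_sweep` object.
#' @param ema EMA records as in [pair_days()].
#' @param min_days per-participant floor on included days.
#' @param conf confidence level.
#' @param boot_n bootstrap resamples for the median CI per cell.
#' @param seed optional RNG seed (one stream across all cells).
#' @return an `agreement_sweep` data frame: one row per (intensity_set, m)
#'   with `mean_kappa`, `sd_kappa`, `median_kappa`, `ci_low`, `ci_high`
#'   (bootstrap median CI), `pooled_kappa`, `pooled_se`, `n_participants`,
#'   `n_days`.
#' @export
sweep_agreement <- function(sweep, ema, min_days = 1L, conf = 0.95,
                            boot_n = 500L, seed = NULL) {
  stopifnot(inherits(sweep, "bout_sweep"))
  base <- data.frame(
    participant_id = sweep$participant_id,
    day_date = sweep$day_date,
    valid = sweep$valid,
    exercise = FALSE,
    stringsAsFactors = FALSE
  )
  # Pair once: inclusion depends only on validity and the EMA response,
  # never on the bout definition; per (set, m) only accel_exercise flips.
  outcomes0 <- pair_days(base, ema)
  day_key <- paste(outcomes0$participant_id, outcomes0$day_date)
  sweep_key <- paste(sweep$participant_id, sweep$day_date)
  day_idx <- match(day_key, sweep_key)
  with_seed(seed, {
    rows <- list()
    for (s in sweep$set_labels) {
      mwa <- sweep$max_window_active[, s]
      for (m in sweep$m_range) {
        outcomes <- outcomes0
        ex <- mwa[day_idx] >= m
        outcomes$accel_exercise[!is.na(outcomes$accel_exercise)] <-
          ex[!is.na(outcomes$accel_exercise)]
        per <- per_participant_kappas(outcomes, min_days = min_days)
        tables <- lapply(seq_len(nrow(per)), function(i) {
          c(a = per$a[i], b = per$b[i], c = per$c[i], d = per$d[i])
        })
        pooled <- pooled_kappa(tables)
        summ <- summarize_kappas(per$kappa, conf = conf, boot_n = boot_n)
        rows[[length(rows) + 1L]] <- data.frame(
          intensity_set = s, m = m,
          mean_kappa = summ$mean, sd_kappa = summ$sd,
          median_kappa = summ$median,
          ci_low = summ$ci_median[1], ci_high = summ$ci_median[2],
          pooled_kappa = pooled$kappa, pooled_se = pooled$se,
          n_participants = summ$n_participants,
          n_days = sum(per$n),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("agreement_sweep", "data.frame")
    out
  })
}
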