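# Person-level correlates of agreement: design construction, univariate
# OLS screens, and the multivariate model (significant-only or
# all-covariates).  Ordinary least squares is fitted with lm(); each
# participant counts once (optional weights = included days).

CORRELATE_PREDICTORS <- c(
  "age", "female", "bmi", "black", "hispanic", "grad_degree", "partner",
  "caregiver", "mean_stress", "tech_use",
  "pct_days_ema", "pct_days_accel", "pct_days_ema_sq", "pct_days_accel_sq"
)

#' Build the per-participant predictor design
#'
#' Merges the covariate table with outcome-derived predictors: the
#' percentage of included days with EMA-reported exercise
#' (`pct_days_ema`) and with accelerometer-classified exercise
#' (`pct_days_accel`), both on a 0--100 scale, plus their squared terms
#' computed after mean-centering (to limit collinearity with the linear
#' terms).  `sex` is recoded to a `female` 0/1 indicator.  Participants
#' with no included days are dropped (their percentages are undefined) and
#' listed in attribute `"dropped"`.
#'
#' @param covariates data frame from [read_covariates()] or
#'   [generate_cohort()].
#' @param outcomes a `daily_outcomes` data frame from [pair_days()].
#' @return a data frame with one row per participant: `participant_id`,
#'   `n_days` (included days), and the predictors listed in
#'   `actema:::CORRELATE_PREDICTORS`.
#' @export
build_design <- function(covariates, outcomes) {
  inc <- outcomes[outcomes$included, , drop = FALSE]
  if (nrow(inc) == 0L) contract_error("no included days; cannot build design")
  sp <- split(inc, inc$participant_id)
  stats_df <- data.frame(
    participant_id = names(sp),
    n_days = vapply(sp, nrow, integer(1)),
    pct_days_ema = vapply(sp, function(d) 100 * mean(d$ema_exercise), numeric(1)),
    pct_days_accel = vapply(sp, function(d) 100 * mean(d$accel_exercise), numeric(1)),
    stringsAsFactors = FALSE
  )
  cov <- covariates
  cov$participant_id <- as.character(cov$participant_id)
  if (!"female" %in% names(cov)) {
    if (!"sex" %in% names(cov)) {
      contract_error("covariates must carry sex or female")
    }
    cov$female <- as.numeric(cov$sex %in% c("female", "1", 1))
  }
  dropped <- setdiff(cov$participant_id, stats_df$participant_id)
  design <- merge(cov, stats_df, by = "participant_id")
  for (col in c("pct_days_ema", "pct_days_accel")) {
    centered <- design[[col]] - mean(design[[col]], na.rm = TRUE)
    design[[paste0(col, "_sq")]] <- centered^2
  }
  design <- design[order(design$participant_id), ]
  rownames(design) <- NULL
  attr(design, "dropped") <- dropped
  design
}

ols_row <- function(y, X_df, predictor_names, model_label, weights = NULL) {
  dat <- cbind(data.frame(.kappa = y), X_df)
  ok <- complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[ok]
  n <- nrow(dat)
  p <- length(predictor_names)
  if (n <= p + 1L) {
    actema_error("insufficient participants for multivariate fit",
                 "actema_contract_error")
  }
  fml <- stats::as.formula(paste(".kappa ~", paste(predictor_names, collapse = " + ")))
  fit <- if (is.null(w)) lm(fml, data = dat) else lm(fml, data = dat, weights = w)
  cf <- summary(fit)$coefficients
  aliased <- setdiff(predictor_names, rownames(cf))
  if (length(aliased)) {
    warning(sprintf("dropped rank-deficient predictor(s): %s",
                    paste(aliased, collapse = ", ")), call. = FALSE)
  }
  kept <- intersect(predictor_names, rownames(cf))
  data.frame(
    predictor = kept,
    beta = cf[kept, "Estimate"],
    se = cf[kept, "Std. Error"],
    p = cf[kept, "Pr(>|t|)"],
    n = n,
    model = model_label,
    stringsAsFactors = FALSE
  )
}

#' Univariate screens of person-level correlates
#'
#' One simple OLS regression of kappa on each predictor; slope, standard
#' error and two-sided t-test p-value per predictor.  A Benjamini-Hochberg
#' adjusted column (`p_bh`) is appended as supplementary output (no
#' correction is applied to the reported p-values).  Zero-variance
#' predictors yield a flagged undefined row.
#'
#' @param kappas data frame with `participant_id` and `kappa` (e.g. the
#'   `per_participant` element of [agreement_analysis()]); undefined
#'   (`NA`) kappas are excluded.
#' @param design data frame from [build_design()].
#' @param predictors character vector of design columns to screen.
#' @param weights optional name of a design column to use as OLS weights
#'   (e.g. `"n_days"`); default unweighted.
#' @return a `kappa_correlates` data frame: `predictor`, `beta`, `se`,
#'   `p`, `n`, `model = "univariate"`, `p_bh`.
#' @export
univariate_screen <- function(kappas, design,
                              predictors = CORRELATE_PREDICTORS,
                              weights = NULL) {
  dat <- merge(kappas[!is.na(kappas$kappa), c("participant_id", "kappa")],
               design, by = "participant_id")
  w <- if (is.null(weights)) NULL else dat[[weights]]
  rows <- lapply(predictors, function(pr) {
    if (!pr %in% names(dat)) {
      contract_error(sprintf("predictor '%s' not in design", pr))
    }
    ok <- !is.na(dat$kappa) & !is.na(dat[[pr]])
    if (sum(ok) < 3L) {
      contract_error(sprintf(
        "need at least 3 participants with kappa and '%s'", pr))
    }
    if (stats::var(dat[[pr]][ok]) == 0) {
      return(data.frame(predictor = pr, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n = sum(ok), model = "univariate",
                        stringsAsFactors = FALSE))
    }
    ols_row(dat$kappa, dat[, pr, drop = FALSE], pr, "univariate",
            weights = w)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("kappa_correlates", "data.frame")
  out
}

#' Multivariate correlate model
#'
#' One OLS fit with either the predictors that were significant in the
#' univariate screens (`mode = "significant_only"`, the default) or all
#' tested correlates simultaneously (`mode = "all_covariates"`).
#' Listwise deletion is applied over the selected predictors; a collinear
#' duplicate predictor is dropped with a warning.
#'
#' @inheritParams univariate_screen
#' @param mode `"significant_only"` or `"all_covariates"`.
#' @param alpha univariate significance threshold used by
#'   `"significant_only"` (default 0.05).
#' @return a `kappa_correlates` data frame with `model` set to
#'   `"multivariate_significant"` or `"multivariate_all"`; empty (zero
#'   rows) when no univariate predictor clears `alpha`.
#' @export
multivariate_model <- function(kappas, design,
                               mode = c("significant_only", "all_covariates"),
                               predictors = CORRELATE_PREDICTORS,
                               alpha = 0.05, weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "significant_only") {
    uni <- univariate_screen(kappas, design, predictors, weights = weights)
    selected <- uni$predictor[!is.na(uni$p) & uni$p < alpha]
    label <- "multivariate_significant"
    if (length(selected) == 0L) {
      out <- data.frame(predictor = character(), beta = numeric(),
                        se = numeric(), p = numeric(), n = integer(),
                        model = character(), stringsAsFactors = FALSE)
      class(out) <- c("kappa_correlates", "data.frame")
      return(out)
    }
  } else {
    selected <- predictors
    label <- "multivariate_all"
  }
  dat <- merge(kappas[!is.na(kappas$kappa), c("participant_id", "kappa")],
               design, by = "participant_id")
  w <- if (is.null(weights)) NULL else dat[[weights]]
  out <- ols_row(dat$kappa, dat[, selected, drop = FALSE], selected, label,
                 weights = w)
  rownames(out) <- NULL
  class(out) <- c("kappa_correlates", "data.frame")
  out
}

#' @export
print.kappa_correlates <- function(x, digits = 3, ...) {
  cat(sprintf("<kappa_correlates> %d row(s)\n", nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
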