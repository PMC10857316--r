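# Person-level correlate regressions: design construction, univariate
# screens, multivariate modes, OLS correctness and parameter recovery.

make_sim_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = rnorm(n, 32, 9), female = rbinom(n, 1, 0.57),
    bmi = rnorm(n, 26, 5), black = rbinom(n, 1, 0.14),
    hispanic = rbinom(n, 1, 0.28), grad_degree = rbinom(n, 1, 0.4),
    partner = rbinom(n, 1, 0.4), caregiver = rbinom(n, 1, 0.49),
    mean_stress = rnorm(n, 22, 6), tech_use = rbinom(n, 1, 0.49),
    pct_days_ema = runif(n, 0, 100), pct_days_accel = runif(n, 0, 100),
    stringsAsFactors = FALSE
  ) |> (\(d) {
    for (col in c("pct_days_ema", "pct_days_accel")) {
      d[[paste0(col, "_sq")]] <- (d[[col]] - mean(d[[col]]))^2
    }
    d
  })()
}

test_that("build_design derives percentage predictors and centered squares", {
  set.seed(3)
  n_days <- 50
  out <- data.frame(
    participant_id = rep(c("P1", "P2", "P3"), each = n_days),
    day_date = rep(as.Date("2020-01-01") + seq_len(n_days) - 1, 3),
    accel_exercise = rbinom(3 * n_days, 1, 0.4) == 1,
    ema_exercise = c(rep(c(TRUE, FALSE), c(20, 30)),
                     rbinom(2 * n_days, 1, 0.5) == 1),
    included = TRUE, stringsAsFactors = FALSE
  )
  cov <- data.frame(participant_id = c("P1", "P2", "P3", "P4"),
                    age = c(30, 40, 50, 60),
                    sex = c("female", "male", "female", "male"),
                    stringsAsFactors = FALSE)
  design <- build_design(cov, out)
  expect_equal(design$pct_days_ema[design$participant_id == "P1"], 40)
  expect_equal(design$female, c(1, 0, 1))
  # P4 has no included days: dropped and logged
  expect_equal(attr(design, "dropped"), "P4")
  # centering: mean of (value - mean) is 0, squares recompute by hand
  centered <- design$pct_days_ema - mean(design$pct_days_ema)
  expect_lt(abs(mean(centered)), 1e-10)
  expect_equal(design$pct_days_ema_sq, centered^2)
})

test_that("univariate screen recovers a simulated sex effect", {
  n <- 200
  design <- make_sim_design(n, seed = 42)
  set.seed(43)
  kappas <- data.frame(
    participant_id = design$participant_id,
    kappa = 0.2 + 0.17 * design$female + rnorm(n, 0, 0.05),
    stringsAsFactors = FALSE
  )
  res <- univariate_screen(kappas, design)
  expect_s3_class(res, "kappa_correlates")
  expect_setequal(res$predictor, actema:::CORRELATE_PREDICTORS)
  fem <- res[res$predictor == "female", ]
  # generating slope inside the fit's own 95% CI
  expect_lt(abs(fem$beta - 0.17), qt(0.975, fem$n - 2) * fem$se)
  expect_lt(fem$p, 1e-6)
})

test_that("a permuted (null) predictor shows no association", {
  n <- 200
  design <- make_sim_design(n, seed = 7)
  set.seed(8)
  kappas <- data.frame(
    participant_id = design$participant_id,
    kappa = 0.2 + 0.17 * design$female + rnorm(n, 0, 0.05),
    stringsAsFactors = FALSE
  )
  design$null_pred <- sample(design$age)  # break any link by permutation
  res <- univariate_screen(kappas, design, predictors = "null_pred")
  expect_lt(abs(res$beta), 3 * res$se)
})

test_that("constant predictors yield a flagged undefined row", {
  design <- make_sim_design(20, seed = 2)
  design$constant <- 1
  kappas <- data.frame(participant_id = design$participant_id,
                       kappa = runif(20), stringsAsFactors = FALSE)
  res <- univariate_screen(kappas, design, predictors = c("age", "constant"))
  expect_true(is.na(res$beta[res$predictor == "constant"]))
  expect_false(is.na(res$beta[res$predictor == "age"]))
})

test_that("OLS via lm matches the closed-form normal equations", {
  set.seed(10)
  design <- make_sim_design(60, seed = 10)
  kappas <- data.frame(participant_id = design$participant_id,
                       kappa = runif(60, -0.2, 0.8), stringsAsFactors = FALSE)
  preds <- c("age", "female", "bmi", "mean_stress")
  res <- multivariate_model(kappas, design, mode = "all_covariates",
                            predictors = preds)
  X <- cbind(1, as.matrix(design[, preds]))
  beta_hat <- solve(crossprod(X), crossprod(X, kappas$kappa))
  expect_equal(res$beta, unname(beta_hat[-1, 1]), tolerance = 1e-8)
})

test_that("regression output is invariant to participant row order", {
  design <- make_sim_design(50, seed = 21)
  set.seed(22)
  kappas <- data.frame(participant_id = design$participant_id,
                       kappa = runif(50), stringsAsFactors = FALSE)
  r1 <- univariate_screen(kappas, design, predictors = c("age", "bmi"))
  perm <- sample(nrow(design))
  r2 <- univariate_screen(kappas[perm, ], design[rev(perm), ],
                          predictors = c("age", "bmi"))
  expect_equal(r1, r2)
})

test_that("multivariate modes behave per contract", {
  n <- 150
  design <- make_sim_design(n, seed = 31)
  set.seed(32)
  kappas <- data.frame(
    participant_id = design$participant_id,
    kappa = 0.1 + 0.3 * design$female + rnorm(n, 0, 0.08),
    stringsAsFactors = FALSE
  )
  uni <- univariate_screen(kappas, design)
  sig <- uni$predictor[!is.na(uni$p) & uni$p < 0.05]
  multi <- multivariate_model(kappas, design, mode = "significant_only")
  expect_setequal(multi$predictor, sig)
  if (identical(sig, "female")) {
    # single selected predictor: multivariate fit IS the univariate fit
    expect_equal(multi$beta, uni$beta[uni$predictor == "female"],
                 tolerance = 1e-12)
  }

  # all-covariates recovery of two independent true effects
  set.seed(33)
  kappas2 <- data.frame(
    participant_id = design$participant_id,
    kappa = 0.1 + 0.25 * design$female + 0.01 * design$mean_stress +
      rnorm(n, 0, 0.05),
    stringsAsFactors = FALSE
  )
  allm <- multivariate_model(kappas2, design, mode = "all_covariates")
  fem <- allm[allm$predictor == "female", ]
  str <- allm[allm$predictor == "mean_stress", ]
  expect_lt(abs(fem$beta - 0.25), qt(0.975, fem$n) * fem$se)
  expect_lt(abs(str$beta - 0.01), qt(0.975, str$n) * str$se)

  # collinear duplicate predictor: dropped with a warning
  design$age_copy <- design$age
  expect_warning(
    dup <- multivariate_model(kappas, design, mode = "all_covariates",
                              predictors = c("age", "age_copy", "female")),
    "rank-deficient"
  )
  expect_false("age_copy" %in% dup$predictor)

  # insufficient participants for the requested predictor count
  expect_error(
    multivariate_model(kappas[1:4, ], design[1:4, ], mode = "all_covariates",
                       predictors = c("age", "bmi", "female", "mean_stress")),
    "insufficient participants"
  )
})

test_that("mean slope estimate is unbiased over replicates at study scale", {
  n <- 79
  beta_true <- 0.17
  betas <- numeric(200)
  set.seed(55)
  for (r in seq_len(200)) {
    design <- data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                         female = rbinom(n, 1, 0.57),
                         stringsAsFactors = FALSE)
    kappas <- data.frame(
      participant_id = design$participant_id,
      kappa = 0.2 + beta_true * design$female + rnorm(n, 0, 0.2),
      stringsAsFactors = FALSE
    )
    res <- univariate_screen(kappas, design, predictors = "female")
    betas[r] <- res$beta
  }
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - beta_true), 2 * mc_se)
})
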