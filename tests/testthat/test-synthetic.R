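# Synthetic cohort generator, analytic-kappa oracle, day-level fast path.

test_that("analytic_kappa matches brute-force enumeration of the joint cells", {
  # independent enumeration over (truth, accel, ema) in {0,1}^3
  enumerate_joint <- function(pi, se_a, sp_a, se_e, sp_e) {
    joint <- matrix(0, 2, 2)  # [ema+1, accel+1] as 0/1 indices offset
    for (s in 0:1) for (a in 0:1) for (e in 0:1) {
      ps <- if (s == 1) pi else 1 - pi
      pa <- if (s == 1) { if (a == 1) se_a else 1 - se_a } else {
        if (a == 1) 1 - sp_a else sp_a }
      pe <- if (s == 1) { if (e == 1) se_e else 1 - se_e } else {
        if (e == 1) 1 - sp_e else sp_e }
      joint[e + 1, a + 1] <- joint[e + 1, a + 1] + ps * pa * pe
    }
    p_o <- joint[1, 1] + joint[2, 2]
    r <- sum(joint[2, ]); s_ <- sum(joint[, 2])
    p_e <- r * s_ + (1 - r) * (1 - s_)
    (p_o - p_e) / (1 - p_e)
  }
  set.seed(64)
  for (i in 1:20) {
    pars <- c(runif(1, 0.05, 0.95), runif(4, 0.55, 0.99))
    expect_equal(do.call(analytic_kappa, as.list(pars))$kappa,
                 do.call(enumerate_joint, as.list(pars)),
                 tolerance = 1e-12)
  }
  # frozen reference point (enumerated by hand: p_o = 0.737, p_e = 0.5585)
  ref <- analytic_kappa(0.3, 0.9, 0.95, 0.7, 0.8)
  expect_equal(ref$p_o, 0.737, tolerance = 1e-12)
  expect_equal(ref$p_e, 0.5585, tolerance = 1e-12)
  expect_equal(ref$kappa, 0.1785 / 0.4415, tolerance = 1e-12)
})

test_that("analytic_kappa edge cases: perfect raters and uninformative EMA", {
  expect_equal(analytic_kappa(0.5, 1, 1, 1, 1)$kappa, 1)
  for (pi in c(0.2, 0.5, 0.8)) {
    # EMA yes-probability independent of the truth => kappa 0
    k <- analytic_kappa(pi, 0.9, 0.95, 0.7, 0.3)
    expect_equal(k$kappa, 0, tolerance = 1e-12)
  }
  expect_error(analytic_kappa(1.2, 1, 1, 1, 1), class = "actema_contract_error")
})

test_that("day_level_generator is deterministic and degenerates gracefully", {
  a <- day_level_generator(0.3, 0.9, 0.95, 0.7, 0.8, n_days = 200, seed = 9)
  b <- day_level_generator(0.3, 0.9, 0.95, 0.7, 0.8, n_days = 200, seed = 9)
  expect_identical(a, b)
  c_ <- day_level_generator(0.3, 0.9, 0.95, 0.7, 0.8, n_days = 200, seed = 10)
  expect_false(identical(a$ema_exercise, c_$ema_exercise))

  one <- day_level_generator(0.3, 0.9, 0.95, 0.7, 0.8, n_days = 1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(cohen_kappa(contingency(one))$undefined)
})

test_that("synthetic_config validates probabilities and bout geometry", {
  expect_error(synthetic_config(ema_sensitivity = 1.4),
               class = "actema_contract_error")
  expect_error(synthetic_config(n_participants = 0),
               class = "actema_contract_error")
  expect_error(synthetic_config(bout_minutes = c(1500, 1600)),
               class = "actema_contract_error")
})

test_that("generate_cohort is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_participants = 3, n_days = 15, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$minutes, b$minutes)
  expect_identical(a$ema, b$ema)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)

  # and written files are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("minutes.csv", "ema.csv", "covariates.csv", "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("cohort files round-trip through the io readers", {
  cfg <- synthetic_config(n_participants = 3, n_days = 10, seed = 5)
  co <- generate_cohort(cfg)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  m <- read_minutes(paths[["minutes"]])
  expect_equal(nrow(m), nrow(co$minutes))
  expect_equal(attr(m, "parse_report")$n_duplicates, 0L)
  e <- read_ema(paths[["ema"]])
  expect_equal(nrow(e), nrow(co$ema))
  expect_equal(e$response, co$ema$response[order(co$ema$participant_id,
                                                 co$ema$report_date)])
  cv <- read_covariates(paths[["covariates"]])
  expect_equal(cv$participant_id, co$covariates$participant_id)
  tr <- read_ground_truth(paths[["ground_truth"]])
  expect_equal(tr$true_exercise, co$truth$true_exercise)
})

test_that("the truth table covers exactly the generated participant-days", {
  cfg <- synthetic_config(n_participants = 4, n_days = 12, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth), 4L * 12L)
  expect_equal(sort(unique(co$truth$participant_id)),
               sort(unique(co$covariates$participant_id)))
  expect_true(all(as.Date(co$ema$report_date) %in% co$truth$day_date))
})

test_that("noiseless cohorts are perfectly identifiable end to end", {
  cfg <- synthetic_config(
    n_participants = 8, n_days = 40,
    ema_sensitivity = 1, ema_specificity = 1,
    ema_compliance = 1, wear_compliance = 1,
    incidental_mvpa_rate = 0, seed = 202
  )
  co <- generate_cohort(cfg)
  out <- process_cohort(co$minutes, co$ema)
  m <- merge(out, co$truth, by = c("participant_id", "day_date"))
  expect_true(all(!is.na(m$accel_exercise)))          # full wear compliance
  expect_equal(m$accel_exercise, m$true_exercise)     # exact recovery
  expect_equal(m$ema_exercise, m$true_exercise)
  fit <- agreement_analysis(out, seed = 1)
  k <- fit$per_participant$kappa
  expect_true(all(k[!is.na(k)] == 1))
})

test_that("uninformative EMA gives mean kappa near zero through the pipeline", {
  cfg <- synthetic_config(
    n_participants = 12, n_days = 60,
    ema_sensitivity = 0.5, ema_specificity = 0.5,
    ema_compliance = 1, wear_compliance = 1, seed = 404
  )
  co <- generate_cohort(cfg)
  out <- process_cohort(co$minutes, co$ema)
  fit <- agreement_analysis(out, seed = 2)
  s <- fit$summary
  expect_lt(abs(s$mean), 3 * s$sd / sqrt(s$n_participants))
})

test_that("accelerometer prevalence tracks the configured prevalence", {
  cfg <- synthetic_config(n_participants = 20, n_days = 60,
                          prevalence_concentration = 0, seed = 88)
  co <- generate_cohort(cfg)
  out <- process_cohort(co$minutes, co$ema)
  inc <- out[!is.na(out$accel_exercise), ]
  p_hat <- mean(inc$accel_exercise)
  mc_se <- sqrt(0.32 * 0.68 / nrow(inc))
  expect_lt(abs(p_hat - 0.32), 4 * mc_se)
})
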