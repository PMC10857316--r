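# Pairing, contingency tables, Cohen's kappa, pooled kappa + SE,
# cross-participant summaries, the sweep agreement table.

test_that("pair_days includes only valid days with a yes/no response", {
  cls <- data.frame(
    participant_id = "P1",
    day_date = as.Date("2020-01-01") + 0:2,
    valid = c(TRUE, FALSE, TRUE),
    exercise = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  ema <- data.frame(
    participant_id = "P1",
    report_date = as.Date("2020-01-01") + 0:2,
    response = c("yes", "yes", "missing"),
    stringsAsFactors = FALSE
  )
  out <- pair_days(cls, ema)
  expect_equal(out$included, c(TRUE, FALSE, FALSE))
  expect_equal(out$accel_exercise, c(TRUE, NA, FALSE))
  expect_equal(out$ema_exercise, c(TRUE, TRUE, NA))
})

test_that("contingency tallies included days in the a/b/c/d orientation", {
  out <- data.frame(
    participant_id = "P1", day_date = as.Date("2020-01-01") + 0:3,
    ema_exercise = c(TRUE, TRUE, FALSE, FALSE),
    accel_exercise = c(TRUE, FALSE, TRUE, FALSE),
    included = TRUE, stringsAsFactors = FALSE
  )
  expect_equal(unclass(contingency(out)), c(a = 1L, b = 1L, c = 1L, d = 1L))

  none <- out[0, ]
  expect_equal(sum(contingency(none)), 0L)

  set.seed(2)
  rnd <- random_outcomes(300)
  t <- contingency(rnd)
  inc <- rnd[rnd$included, ]
  expect_equal(unname(t["a"]), sum(inc$ema_exercise & inc$accel_exercise))
  expect_equal(unname(t["d"]), sum(!inc$ema_exercise & !inc$accel_exercise))
  expect_equal(sum(t), nrow(inc))
})

test_that("cohen_kappa reproduces hand-computed values and edge cases", {
  k <- cohen_kappa(c(50, 10, 10, 30))
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.52)
  expect_equal(k$kappa, 7 / 12, tolerance = 1e-12)

  expect_equal(cohen_kappa(c(40, 0, 0, 25))$kappa, 1)
  expect_equal(cohen_kappa(c(9, 21, 21, 49))$kappa, 0, tolerance = 1e-12)

  expect_true(cohen_kappa(c(0, 0, 0, 0))$undefined)
  expect_match(cohen_kappa(c(0, 0, 0, 0))$reason, "no included days")
  expect_true(cohen_kappa(c(5, 3, 0, 0))$undefined)  # EMA constant ("yes")
  expect_true(cohen_kappa(c(40, 0, 0, 0))$undefined) # both constant
})

test_that("kappa is symmetric under transposition and scale-invariant", {
  set.seed(77)
  for (i in 1:25) {
    t <- sample(0:40, 4, replace = TRUE)
    if (sum(t) == 0) next
    k1 <- cohen_kappa(t)
    k2 <- cohen_kappa(t[c(1, 3, 2, 4)])  # swap rater roles (b <-> c)
    expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
    k3 <- cohen_kappa(t * 7)
    if (!k1$undefined) expect_equal(k1$kappa, k3$kappa, tolerance = 1e-12)
  }
})

test_that("cohen_kappa agrees with an independent implementation", {
  set.seed(41)
  for (i in 1:25) {
    t <- sample(1:60, 4, replace = TRUE)
    m <- matrix(t, 2, 2, byrow = TRUE)
    expect_equal(cohen_kappa(t)$kappa, e1071::classAgreement(m)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("pooled_kappa conserves counts and scales its SE as 1/sqrt(k)", {
  t1 <- c(a = 30, b = 8, c = 12, d = 50)
  single <- pooled_kappa(list(t1))
  expect_equal(single$kappa, cohen_kappa(t1)$kappa)

  two <- pooled_kappa(list(t1, t1))
  expect_equal(two$kappa, single$kappa, tolerance = 1e-12)
  expect_equal(two$se, single$se / sqrt(2), tolerance = 1e-9)

  t2 <- c(a = 5, b = 9, c = 2, d = 11)
  pooled <- pooled_kappa(list(t1, t2))
  expect_equal(unclass(attr(pooled, "table")),
               unclass(as_tbl <- t1 + t2))
  expect_equal(pooled$n, sum(t1) + sum(t2))
})

test_that("asymptotic pooled SE is close to the bootstrap SE", {
  t <- c(a = 5000, b = 1000, c = 1000, d = 3000)
  pk <- pooled_kappa(list(t))
  bs <- kappa_bootstrap_se(t, boot_n = 2000, seed = 19)
  expect_lt(abs(pk$se - bs) / bs, 0.10)
})

test_that("summarize_kappas handles moments, undefined values and seeding", {
  s <- summarize_kappas(c(0.2, 0.4), seed = 1)
  expect_equal(s$mean, 0.3)
  expect_equal(s$median, 0.3)
  expect_equal(s$min, 0.2)
  expect_equal(s$max, 0.4)

  s2 <- summarize_kappas(c(0.2, 0.4, NA), seed = 1)
  expect_equal(s2$n_participants, 2L)
  expect_equal(s2$n_undefined, 1L)
  expect_equal(s2$mean, 0.3)

  set.seed(6)
  ks <- rnorm(40, 0.3, 0.2)
  a <- summarize_kappas(ks, seed = 99)
  b <- summarize_kappas(ks, seed = 99)
  expect_identical(a$ci_median, b$ci_median)

  empty <- summarize_kappas(c(NA_real_, NA_real_))
  expect_true(empty$empty)
  expect_equal(empty$n_undefined, 2L)
})

test_that("agreement_analysis composes per-participant and pooled results", {
  out <- day_level_generator(0.35, 0.92, 0.93, 0.75, 0.8, n_days = 600, seed = 8)
  out$participant_id <- rep(sprintf("P%d", 1:6), each = 100)
  fit <- agreement_analysis(out, seed = 4)
  expect_equal(nrow(fit$per_participant), 6L)
  expect_equal(fit$n_days, 600L)
  # pooled table equals the sum of participant tables
  pooled_tab <- attr(fit$pooled, "table")
  manual <- Reduce(`+`, lapply(split(out, out$participant_id),
                               function(d) unclass(contingency(d))))
  expect_equal(unclass(pooled_tab), manual)
  # per-participant kappas match direct computation
  k3 <- cohen_kappa(contingency(out[out$participant_id == "P3", ]))
  expect_equal(fit$per_participant$kappa[3], k3$kappa)
})

test_that("empirical pooled kappa converges to the analytic oracle", {
  pars <- list(prevalence = 0.3, accel_sensitivity = 0.9,
               accel_specificity = 0.95, ema_sensitivity = 0.7,
               ema_specificity = 0.8)
  analytic <- do.call(analytic_kappa, pars)$kappa
  out <- do.call(day_level_generator, c(pars, list(n_days = 12807, seed = 123)))
  emp <- pooled_kappa(list(contingency(out)))
  expect_lt(abs(emp$kappa - analytic), 3 * emp$se)
})

test_that("sweep_agreement yields a full grid with constant inclusion", {
  # perfect-agreement construction: accel truth uses a 24-min bout rule
  # and EMA reports the truth
  set.seed(14)
  n_per <- 40
  parts <- sprintf("P%d", 1:6)
  ts0 <- as.POSIXct("2020-02-01 03:00", tz = "UTC")
  minutes <- list(); ema <- list()
  for (p in seq_along(parts)) {
    for (d in 1:n_per) {
      ex <- runif(1) < 0.5
      intensity <- rep(0L, 1440L)
      if (ex) intensity[600:625] <- 2L  # 26 MVPA minutes
      ts <- ts0 + 86400 * (d - 1) + 60 * (0:1439)
      minutes[[length(minutes) + 1L]] <- data.frame(
        participant_id = parts[p], timestamp = ts,
        steps = sample(10:30, 1440, TRUE) + ifelse(intensity > 0, 80L, 0L),
        intensity = intensity, stringsAsFactors = FALSE)
      ema[[length(ema) + 1L]] <- data.frame(
        participant_id = parts[p],
        report_date = as.Date("2020-02-01") + d - 1,
        response = if (ex) "yes" else "no", stringsAsFactors = FALSE)
    }
  }
  days <- finalize_days(build_social_days(do.call(rbind, minutes)))
  sw <- sweep_definitions(days)
  res <- sweep_agreement(sw, do.call(rbind, ema), seed = 2)
  expect_equal(nrow(res), 3L * 16L)
  # inclusion does not depend on m
  expect_equal(length(unique(res$n_days)), 1L)
  # kappa = 1 for every m <= 26 under MVPA (bouts are 26 contiguous minutes)
  mv <- res[res$intensity_set == "moderate+vigorous" & res$m <= 26, ]
  expect_true(all(mv$mean_kappa == 1))
  expect_true(all(mv$pooled_kappa == 1))
  # and no exercise day at all under vigorous-only: kappa undefined
  vg <- res[res$intensity_set == "vigorous", ]
  expect_true(all(is.na(vg$pooled_kappa)))
})
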