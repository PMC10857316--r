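---
title: "Methods: day-level concordance of EMA and accelerometer exercise measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-level concordance of EMA and accelerometer exercise measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actema)
```

## The measurement problem

Long-term exercise monitoring faces a trade-off: accelerometers give an
objective minute-by-minute record but burden the wearer (daily wear,
charging, syncing), while a single end-of-day smartphone prompt — "Did you
exercise today for 30 min or more at a moderate or vigorous level?" — is
nearly free but is a self-report.  actema implements the analysis that
validation studies use to decide whether the cheap measure can stand in for
the expensive one at *day* resolution: classify each day twice
(device-based and self-reported), and quantify chance-corrected agreement
with Cohen's kappa, per person and pooled over all person-days.

## Day construction

**Social day.**  The analysis day runs from 03:00 to 02:59 the next civil
morning, so that an evening workout and the end-of-day report about it fall
on the same unit.  `assign_social_day()` labels a timestamp with the date
on which its social day starts.  All times are naive civil clock times; no
timezone arithmetic is applied (internally times are stored as UTC purely
as a tz-free container).  If a clock anomaly maps two civil minutes onto
one slot, the first record wins, consistent with the reader's
de-duplication rule.

**Non-wear.**  A continuously worn tracker registers some steps in almost
every waking hour, so a long stretch with essentially no steps is read as
"device off".  The rule is: more than 60 consecutive minutes with fewer
than 10 steps.  Two readings of the step criterion are implemented, because
the phrase genuinely underdetermines it:

* `run_total` (default): a minute is non-wear when it lies in *some* span
  of at least 61 consecutive minutes whose **total** steps are below 10.
  This attaches "fewer than 10 steps" to the whole span.  We rejected the
  superficially similar formulation "maximal runs of individually-low
  minutes, then check the run total", because neighbouring minutes with
  1–9 steps would join such runs and inflate their totals; a completely
  unobserved night flanked by two or three low-step minutes would then fail
  the total test and count as *wear*, which is plainly not what a non-wear
  rule intends.  Under the span reading, a single minute carrying 10+ steps
  can never be absorbed, so it splits candidate runs — matching the
  intuition that real steps interrupt a non-wear episode.
* `per_minute`: maximal runs of minutes that are *each* below 10 steps
  (or unobserved), longer than 60 minutes.

Both interpretations agree on the canonical cases (61 zero-step minutes are
non-wear; exactly 60 are wear; one 9-step minute inside a zero run does not
rescue it).  They differ when several low-but-nonzero minutes are spread
through a run.  Neither is asserted to be the historically intended rule;
the choice is a config key (`nonwear$interpretation`).

Unobserved slots (no data row) are treated as zero-step sedentary minutes:
they join non-wear runs, but a short gap (at or under 60 minutes) embedded
in otherwise active data stays wear — deleting brief sync gaps would
penalise well-worn days.  Runs are computed within a social day and never
bridge the 02:59→03:00 boundary, keeping days independent.

**Validity.**  A day is valid with at least 600 wear minutes (10 h,
boundary inclusive: 600 is valid, 599 is not).  Only valid days with a
yes/no EMA response enter agreement analyses.

## Exercise-day classification

A day is an exercise day when any consecutive `W`-minute window contains at
least `m` active minutes; the primary definition is `m = 24`, `W = 30`,
active = moderate or vigorous (MVPA).  The 24-of-30 form tolerates up to
6 below-threshold minutes (water breaks, traffic lights) inside a bout.
`max_window_active()` computes the windowed maximum with a running sum
(O(1440) per day) and is validated against brute-force enumeration of all
windows; windows are confined to the 1440-slot day.  Non-wear minutes are
gated out *before* counting, so intensity labels recorded while the device
sat on a shelf cannot create exercise days; window positions are not
otherwise restricted to fully worn spans, since total wear is screened
separately by the validity rule.

`sweep_definitions()` computes the windowed maximum once per day per
intensity set and thresholds it at every `m` in 15..30 — classification is
monotone: non-increasing in `m`, non-decreasing under intensity-set
inclusion (vigorous ⊂ MVPA ⊂ all intensities).

## Agreement

For a participant's included days, the 2×2 table (a = both yes, b = EMA
yes only, c = device yes only, d = both no) gives

$$\kappa = \frac{p_o - p_e}{1 - p_e}, \qquad
p_o = \frac{a+d}{n}, \quad p_e = rs + (1-r)(1-s),$$

with marginals \(r = (a+b)/n\), \(s = (a+c)/n\).  A participant for whom
either measure never varies has a degenerate marginal; such kappas are
reported as *undefined* and excluded from cross-participant moments (their
count is surfaced) rather than imputed as zero, which would bias the mean.
Note that when exactly one measure is constant the formula would return 0;
we flag it instead, because a constant measure carries no information about
chance-corrected agreement.

The pooled kappa is Cohen's kappa of the element-wise sum of the
per-participant tables.  Its standard error uses the large-sample
(Fleiss–Cohen–Everitt) variance

$$\widehat{\mathrm{Var}}(\hat\kappa) = \frac{
  \sum_i p_{ii}\big[(1-p_e) - (p_{.i}+p_{i.})(1-p_o)\big]^2
  + (1-p_o)^2 \sum_{i \ne j} p_{ij}(p_{.i}+p_{j.})^2
  - (p_o p_e - 2p_e + p_o)^2}{N (1-p_e)^4},$$

which scales exactly as \(1/\sqrt{N}\) under table replication; a
multinomial bootstrap SE (`kappa_bootstrap_se()`) is available as a
cross-check and agrees within a few percent on large tables.

Cross-participant summaries report both the mean (with a t-interval) and
the median (with a seeded percentile-bootstrap interval): the mean is the
conventional headline number, while sweep figures in this literature are
usually drawn as median ± 95% CI, so `plot()` on a sweep defaults to the
median.  Whether such intervals should be across-participant percentiles
or bootstrap CIs of the median is a free choice; we use the bootstrap CI
of the median and label it as such.

## Correlates of agreement

Person-level kappas are regressed on covariates (age, sex, BMI, race,
ethnicity, education, partner, caregiver status, mean perceived stress,
health-tech use) plus outcome-derived predictors: the percentage of
included days with exercise by each measure (0–100 scale) and their
squared terms.  Squared terms are computed after mean-centering to limit
collinearity with the linear terms.  Univariate OLS screens come first;
the multivariate stage is implemented in *both* plausible forms —
`significant_only` (univariate p < 0.05 predictors) and `all_covariates`
(every tested correlate simultaneously) — because the two conventions
differ and the package does not guess between them; every output row is
labelled with its model.  Fits are unweighted (each participant counts
once) with an optional `weights = "n_days"` mode; p-values come from the
usual t-distribution with no multiplicity correction, and a
Benjamini–Hochberg column is appended to the univariate output as clearly
supplementary.  Listwise deletion applies to missing covariates;
rank-deficient predictors are dropped with a warning.

## The synthetic cohort

`generate_cohort()` produces minute streams, EMA responses and covariates
with known ground truth, so the whole pipeline is testable without any
wearable data.  Its defaults describe the emulated study population:

| parameter | default | rationale |
|---|---|---|
| participants × days | 79 × 365 | cohort size and follow-up length |
| exercise prevalence | mean 0.32, Beta concentration 7 | cohort mean 32% of days; concentration 7 gives between-person SD ≈ 0.165 |
| bout duration | uniform 25–60 MVPA min, ≤ 6 rest min | recreational bouts clearing the 24-min criterion |
| EMA compliance | 0.64 | observed end-of-day response rate |
| wear compliance | 0.68 | observed fraction of valid-wear days |
| EMA sensitivity / specificity | 0.631 / 0.745 | see below |

The EMA error rates are not free knobs: with the device essentially
reporting the truth, requiring the model to reproduce the cohort's EMA
yes-rate (37.5%) *and* its pooled agreement (κ ≈ 0.36) at prevalence 0.32
fixes them analytically —
\(\pi\,se + (1-\pi)(1-sp) = 0.375\) and \(\kappa(\pi, se, sp) = 0.36\)
solve to \(se = 0.631\), \(sp = 0.745\).

Mechanics per participant-day: a worn day gets a continuous daytime span
(start 06:00–08:00, 700–1020 observed minutes) of sedentary minutes with
Poisson(6) steps and occasional light-intensity minutes (rate 0.18,
Poisson(45) steps); an unworn day gets at most 500 observed minutes and can
never reach validity.  On a true exercise day that is worn, one MVPA bout
(steps Poisson(110), 30% vigorous minutes) is placed uniformly in the span;
its first 24 minutes are contiguous MVPA and any embedded rest minutes come
after them, so a genuine bout always satisfies the primary rule.  Optional
extra non-wear runs (Poisson-many per day, 61–180 minutes) are carved out
of the span, capped so a worn day keeps at least 620 wear minutes.  The
accelerometer's error is therefore mechanistic (bout length near the
threshold, masking) in the full generator, while `day_level_generator()`
draws day outcomes directly from a parametric two-noisy-raters model whose
closed-form kappa `analytic_kappa()` provides the oracle:
\(P(A,E) = \pi f_A f_E + (1-\pi) f_A f_E\) under conditional independence
given the latent state.

What the generator does *not* emulate: circadian and weekday structure,
weather, multi-bout days (configurable but off by default), physiologic
step waveforms, autocorrelated compliance (missingness is independent
Bernoulli), or any dependence of covariates on agreement (covariates match
the cohort's margins but carry no built-in joint structure, so correlate
regressions on default synthetic data estimate nulls).  Passing tests
therefore demonstrate that the *machinery* is correct — boundaries, window
arithmetic, kappa algebra, recovery of known truth — not that real wearable
data meet the model's assumptions.

## Numerical and design choices

* Duplicate minutes: first occurrence (in file order) wins, count logged;
  EMA duplicate days resolve by latest completion time, then first row.
* Missing minutes are never imputed at read time; day assembly records
  them as unobserved.
* Degenerate kappas: flagged, excluded from moments, counted — never
  imputed.
* The per-participant inclusion floor defaults to 1 included day
  (`agreement$min_days_per_participant`), since no floor is part of the
  primary definition; it is configurable.
* OLS is validated against the closed-form normal equations at 1e-8;
  regression output is invariant to row order.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; a fixed config + seed reproduces cohorts
  byte-identically.
* Problem sizes in the test suite: window-oracle equivalence runs on
  1,000 random days; the noiseless identifiability check runs the full
  79 × 365 cohort; convergence checks use 12,807 simulated person-days,
  matching the emulated study's included-day count; regression recovery
  uses 200 replicates.  These sizes keep the full suite comfortably
  re-runnable on a laptop while leaving Monte-Carlo error well inside the
  asserted tolerances.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_participants = 10, n_days = 60, seed = 42)
cohort <- generate_cohort(cfg)
outcomes <- process_cohort(cohort$minutes, cohort$ema)
fit <- agreement_analysis(outcomes, seed = 1)
fit

days <- finalize_days(build_social_days(cohort$minutes))
sweep <- sweep_agreement(sweep_definitions(days), cohort$ema, seed = 1)
plot(sweep)
```

## Known limitations

* The non-wear rule's two readings can disagree on real data with many
  low-step minutes; results should state which interpretation was used.
* The pooled SE is asymptotic; for small pooled tables prefer the
  bootstrap.
* Median bootstrap CIs are percentile intervals; with very few
  participants they can be degenerate.
* The correlate models are descriptive associations at n ≈ 79; the
  package deliberately offers no causal or mixed-effects machinery.
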