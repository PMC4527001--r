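# Synthetic cohort and raw-signal generators.

test_that("generation is a pure function of spec and seed", {
  s <- cohort_spec(n_participants = 25, seed = 13)
  c1 <- generate_paired_cohort(s)
  c2 <- generate_paired_cohort(s)
  expect_identical(c1$accelerometer, c2$accelerometer)
  expect_identical(c1$questionnaire, c2$questionnaire)
  c3 <- generate_paired_cohort(cohort_spec(n_participants = 25, seed = 14))
  expect_false(identical(c1$accelerometer, c3$accelerometer))
})

test_that("every generated record satisfies the budget invariants", {
  coh <- generate_paired_cohort(cohort_spec(n_participants = 40, seed = 2))
  for (df in list(coh$accelerometer, coh$questionnaire)) {
    expect_equal(df$sedentary_min + df$lpa_min + df$mpa_min + df$vpa_min,
                 rep(1440, nrow(df)), tolerance = 1e-9)
    expect_true(all(df[c("sedentary_min", "lpa_min", "mpa_min",
                         "vpa_min")] >= 0))
    expect_equal(df$mvpa_min, df$mpa_min + df$vpa_min)
    expect_equal(df$sedentary_light_min, df$sedentary_min + df$lpa_min)
  }
  # 24-h MET-h bookkeeping of the generated questionnaire records
  q <- coh$questionnaire
  expect_equal(q$total_met_h_24,
               (1.3 * q$sedentary_min + 2.3 * q$lpa_min +
                  4 * q$mpa_min + 7.5 * q$vpa_min) / 60)
})

test_that("questionnaire means scale with the over-reporting factors", {
  base <- cohort_spec(n_participants = 2000, seed = 6,
                      overreport_factor_mpa = 1, overreport_factor_vpa = 1)
  doubled <- cohort_spec(n_participants = 2000, seed = 6,
                         overreport_factor_mpa = 2,
                         overreport_factor_vpa = 3)
  c1 <- generate_paired_cohort(base)
  c2 <- generate_paired_cohort(doubled)
  q1 <- c1$questionnaire[c1$questionnaire$admission == 1, ]
  q2 <- c2$questionnaire[c2$questionnaire$admission == 1, ]
  expect_equal(mean(q2$mpa_min) / mean(q1$mpa_min), 2, tolerance = 1e-9)
  expect_equal(mean(q2$vpa_min) / mean(q1$vpa_min), 3, tolerance = 1e-9)
  # and sit near the accelerometer scale times the factor
  a2 <- c2$accelerometer[c2$accelerometer$period == 1, ]
  expect_equal(mean(q2$mpa_min) / mean(a2$mpa_min), 2, tolerance = 0.1)
})

test_that("the noise-free unbiased limit reproduces ranks exactly", {
  s <- cohort_spec(n_participants = 50,
                   target_spearman = c(sedentary = 1, mpa = 1, vpa = 1),
                   target_icc_accelerometer = 1,
                   target_icc_questionnaire = 1,
                   overreport_factor_mpa = 1, overreport_factor_vpa = 1,
                   sed_share_quest = 0.567,  # same reporting behaviour
                   seed = 4)
  coh <- generate_paired_cohort(s)
  acc <- coh$accelerometer; qu <- coh$questionnaire
  for (col in c("sedentary_min", "lpa_min", "mpa_min", "vpa_min",
                "mvpa_min")) {
    r <- cor(qu[[col]][qu$admission == 1],
             (acc[[col]][acc$period == 1] + acc[[col]][acc$period == 2]) / 2,
             method = "spearman")
    expect_equal(r, 1, tolerance = 1e-12)
  }
  # both periods identical at ICC 1
  expect_equal(acc$vpa_min[acc$period == 1], acc$vpa_min[acc$period == 2],
               tolerance = 1e-12)
})

test_that("generated cohorts recover their Spearman and ICC targets", {
  # small-scale recovery check (the acceptance suite runs the full one)
  sp <- icc <- numeric(40)
  for (i in 1:40) {
    coh <- generate_paired_cohort(cohort_spec(seed = 300 + i))
    acc <- coh$accelerometer; qu <- coh$questionnaire
    av <- (acc$vpa_min[acc$period == 1] + acc$vpa_min[acc$period == 2]) / 2
    sp[i] <- cor(qu$vpa_min[qu$admission == 1], av, method = "spearman")
    icc[i] <- icc_anova(acc$mpa_min[acc$period == 1],
                        acc$mpa_min[acc$period == 2])$icc
  }
  expect_equal(mean(sp), 0.54, tolerance = 0.05)
  expect_equal(mean(icc), 0.78, tolerance = 0.05)
})

test_that("raw-day generation round-trips through the epoch pipeline", {
  model <- printed_model()
  # all-day MET 1.5: processed epochs average near the cut point 166.5
  rec <- generate_raw_day(constant_schedule(1.5), model, seed = 19)
  es <- compute_epoch_series(rec)
  expect_equal(nrow(es), 1440)
  expect_equal(mean(es$svm_gs), 166.5, tolerance = 0.05 * 166.5)

  # zero-deviation day: every epoch zero, a fully sedentary day
  m0 <- list(slope = 1, intercept = -100)
  expect_warning(rec0 <- generate_raw_day(constant_schedule(1, 60), m0,
                                          seed = 1),
                 "clamping")
  es0 <- compute_epoch_series(rec0)
  expect_equal(es0$svm_gs, rep(0, 60))

  # different seeds: different signals, same schedule-level expectation
  r1 <- generate_raw_day(constant_schedule(3, 120), model, seed = 1)
  r2 <- generate_raw_day(constant_schedule(3, 120), model, seed = 2)
  expect_false(identical(r1$x, r2$x))
  e1 <- mean(compute_epoch_series(r1)$svm_gs)
  e2 <- mean(compute_epoch_series(r2)$svm_gs)
  expect_equal(e1, 960, tolerance = 0.05 * 960)
  expect_equal(e2, 960, tolerance = 0.05 * 960)
})

test_that("a scheduled mixed day classifies into its scheduled minutes", {
  model <- printed_model()
  cuts <- derive_cutpoints(model)
  sched <- day_schedule(start_minute = c(0, 1200, 1260, 1380),
                        duration_min = c(1200, 60, 120, 60),
                        met = c(1.2, 2, 4, 7))
  rec <- generate_raw_day(sched, model, noise_shape = 64, seed = 23)
  day <- extract_complete_days(compute_epoch_series(rec), 1)[[1]]
  s <- summarize_day(day, cuts)
  # low noise: nearly all minutes fall in their scheduled category
  expect_equal(s$sedentary_min, 1200, tolerance = 0.02 * 1200)
  expect_equal(s$mpa_min, 120, tolerance = 6)
  expect_equal(s$vpa_min, 60, tolerance = 4)
  expect_equal(s$sedentary_min + s$lpa_min + s$mpa_min + s$vpa_min, 1440)
})

test_that("schedules validate coverage and overlap", {
  expect_error(day_schedule(c(0, 50), c(60, 60), c(1, 2)), "overlap")
  expect_error(day_schedule(c(0, 70), c(60, 60), c(1, 2)), "gaps")
  expect_error(generate_raw_day(day_schedule(10, 60, 2), printed_model()),
               "minute 0")
})

test_that("simulated calibration bouts recover the generating line", {
  model <- printed_model()
  obs <- generate_calibration_bouts(model, n_participants = 22,
                                    cv = 0.15, seed = 29)
  expect_equal(nrow(obs), 22 * 5)
  fit <- fit_calibration(obs)
  expect_equal(fit$slope, model$slope, tolerance = 0.1 * model$slope)
  expect_equal(fit$intercept, model$intercept,
               tolerance = 0.25 * abs(model$intercept))
})
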