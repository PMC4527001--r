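# Agreement statistics: Spearman + bootstrap CI, Bland-Altman, weighted
# kappa on quartiles, one-way ANOVA ICC, report assembly.

test_that("Spearman point estimate equals the rank-then-Pearson oracle", {
  expect_equal(spearman_with_ci(1:3, c(2, 4, 6), n_boot = 100)$r, 1)
  expect_equal(spearman_with_ci(1:3, c(3, 2, 1), n_boot = 100)$r, -1)
  set.seed(41)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  est <- spearman_with_ci(a, b, n_boot = 100, seed = 1)
  expect_equal(est$r, cor(a, b, method = "spearman"), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(spearman_with_ci(exp(a), b^3 + 5 * b, n_boot = 100,
                                seed = 1)$r, est$r, tolerance = 1e-12)
  expect_error(spearman_with_ci(rep(1, 10), rnorm(10), n_boot = 100),
               "constant")
})

test_that("bootstrap CI is seeded, ordered and brackets the estimate", {
  set.seed(55)
  a <- rnorm(60); b <- 0.6 * a + rnorm(60, 0, 0.8)
  e1 <- spearman_with_ci(a, b, n_boot = 500, seed = 7)
  e2 <- spearman_with_ci(a, b, n_boot = 500, seed = 7)
  expect_identical(e1, e2)
  expect_lt(e1$ci_low, e1$ci_high)
  expect_true(e1$ci_low <= e1$r && e1$r <= e1$ci_high)
  # the bootstrap must not disturb the global RNG stream
  set.seed(3); before <- rnorm(1)
  set.seed(3); invisible(spearman_with_ci(a, b, n_boot = 100, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("Bland-Altman limits are mean difference +/- 2 SD", {
  x <- c(3, 7, 1, 9)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_difference, 0)
  expect_equal(c(ba$lower_limit, ba$upper_limit), c(0, 0))

  ba <- bland_altman(x, x - 5)
  expect_equal(ba$mean_difference, 5)
  expect_equal(ba$sd_difference, 0)

  set.seed(61)
  a <- rnorm(40, 100, 20); b <- rnorm(40, 90, 15)
  ba <- bland_altman(a, b, ids = paste0("p", 1:40))
  expect_equal(ba$mean_difference, mean(a - b))
  expect_equal(ba$sd_difference, sd(a - b))
  expect_equal(ba$lower_limit, mean(a - b) - 2 * sd(a - b))
  expect_equal(ba$points$mean, (a + b) / 2)
  expect_equal(ba$points$difference, a - b)
  # Chebyshev: at least 75% of points inside +/- 2 SD
  inside <- ba$points$difference >= ba$lower_limit &
    ba$points$difference <= ba$upper_limit
  expect_gte(mean(inside), 0.75)
})

test_that("quartile cutting sends cut-equal values to the lower class", {
  set.seed(71)
  x <- rnorm(100)
  expect_equal(accelq:::.quartile_classes(x), oracle_quartiles(x))
  # a value exactly at the first quartile lands in class 1
  x[1] <- quantile(x[-1], 0.25)
  cl <- accelq:::.quartile_classes(x)
  expect_lte(cl[1], 2L)  # never above the cut's class
})

test_that("weighted kappa equals the direct contingency-table formula", {
  set.seed(81)
  a <- rnorm(200); b <- a + rnorm(200, 0, 0.8)
  wk <- weighted_kappa_quartiles(a, b)
  tab <- table(oracle_quartiles(a), oracle_quartiles(b))
  expect_equal(wk$kappa, oracle_weighted_kappa(tab), tolerance = 1e-12)
  wkq <- weighted_kappa_quartiles(a, b, weights = "quadratic")
  expect_equal(wkq$kappa, oracle_weighted_kappa(tab, linear = FALSE),
               tolerance = 1e-12)
  expect_equal(wk$same_quartile_pct,
               100 * mean(oracle_quartiles(a) == oracle_quartiles(b)))
})

test_that("kappa is 1 iff the quartile assignments agree everywhere", {
  set.seed(91)
  a <- rnorm(100)
  wk <- weighted_kappa_quartiles(a, a)
  expect_equal(wk$kappa, 1)
  expect_equal(wk$same_quartile_pct, 100)
  # monotone relabeling of both series leaves kappa unchanged
  wk2 <- weighted_kappa_quartiles(exp(a), exp(a))
  expect_equal(wk2$kappa, 1)
})

test_that("kappa on independent series is within 3 SE of zero", {
  set.seed(101)
  a <- rnorm(10000); b <- rnorm(10000)
  wk <- weighted_kappa_quartiles(a, b)
  expect_lt(abs(wk$kappa), 3 * wk$se0)
  expect_error(weighted_kappa_quartiles(rep(1, 20), rnorm(20)),
               "degenerate")
})

test_that("ICC equals hand-computed one-way ANOVA mean squares", {
  # identical replicates, variation between participants: ICC = 1
  x <- c(10, 20, 30, 40)
  expect_equal(icc_anova(x, x)$icc, 1)

  first <- c(10, 12, 25, 31)
  second <- c(11, 14, 22, 35)
  est <- icc_anova(first, second)
  expect_equal(est$icc, oracle_icc(first, second), tolerance = 1e-12)
  expect_true(est$ci_low <= est$icc && est$icc <= est$ci_high)
  expect_error(icc_anova(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("the F-interval covers the true ICC at its nominal rate", {
  # one-way random effects with variance ratio 0.78
  rho <- 0.78
  hits <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    person <- rnorm(148, 0, sqrt(rho))
    reps <- person + matrix(rnorm(296, 0, sqrt(1 - rho)), 148, 2)
    ci <- icc_anova(reps[, 1], reps[, 2])
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ICC estimate converges to the variance ratio at large n", {
  set.seed(111)
  rho <- 0.6
  person <- rnorm(5000, 0, sqrt(rho))
  reps <- person + matrix(rnorm(10000, 0, sqrt(1 - rho)), 5000, 2)
  expect_equal(icc_anova(reps[, 1], reps[, 2])$icc, rho, tolerance = 0.02)
})

test_that("the assembled report matches componentwise statistics", {
  coh <- generate_paired_cohort(cohort_spec(n_participants = 30,
                                            seed = 77))
  rep1 <- build_report(coh$accelerometer, coh$questionnaire,
                       n_boot = 200, seed = 5)
  rep2 <- build_report(coh$accelerometer, coh$questionnaire,
                       n_boot = 200, seed = 5)
  expect_identical(rep1$validity, rep2$validity)  # determinism

  acc <- coh$accelerometer; qu <- coh$questionnaire
  ids <- sort(unique(acc$participant_id))
  q1 <- qu$mvpa_min[qu$admission == 1][match(ids,
         qu$participant_id[qu$admission == 1])]
  am <- (acc$mvpa_min[acc$period == 1] + acc$mvpa_min[acc$period == 2]) / 2
  row <- rep1$validity[rep1$validity$category == "MVPA", ]
  expect_equal(row$spearman_r, cor(q1, am, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(row$mean_difference, mean(q1 - am), tolerance = 1e-12)
  expect_equal(row$kappa, weighted_kappa_quartiles(q1, am)$kappa,
               tolerance = 1e-12)
  icc_row <- rep1$reliability[rep1$reliability$method == "accelerometer" &
                                rep1$reliability$category == "MVPA", ]
  expect_equal(icc_row$icc,
               icc_anova(acc$mvpa_min[acc$period == 1],
                         acc$mvpa_min[acc$period == 2])$icc,
               tolerance = 1e-12)
  # descriptives: mean of the first accelerometer MVPA
  d <- rep1$descriptives
  expect_equal(d$mean[d$category == "MVPA" &
                        d$series == "first accelerometer"],
               mean(acc$mvpa_min[acc$period == 1]), tolerance = 1e-12)
})

test_that("misaligned participant IDs are rejected by name", {
  coh <- generate_paired_cohort(cohort_spec(n_participants = 10, seed = 3))
  bad <- coh$questionnaire
  bad$participant_id[bad$admission == 2][1] <- 999
  expect_error(build_report(coh$accelerometer, bad, n_boot = 200),
               "999")
})

test_that("report tables are written as CSV files", {
  coh <- generate_paired_cohort(cohort_spec(n_participants = 20, seed = 9))
  rep <- build_report(coh$accelerometer, coh$questionnaire,
                      n_boot = 200, seed = 1)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_report_csv(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("descriptives.csv", "validity.csv", "reliability.csv",
      "bland_altman_mvpa.csv")))))
  pts <- utils::read.csv(file.path(dir, "bland_altman_vpa.csv"))
  expect_equal(nrow(pts), 20)
  expect_equal(names(pts), c("participant_id", "mean", "difference"))
})
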