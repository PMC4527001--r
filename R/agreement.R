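# Method-agreement statistics for paired per-participant measurements:
# Spearman correlation with percentile-bootstrap CI, Bland-Altman limits
# of agreement at +/- 2 SD, weighted kappa on per-method quartiles, and
# the one-way ANOVA intraclass correlation for test-retest reliability.

# run expr with a temporary RNG state seeded from `seed` (NULL = leave
# the global stream alone)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Spearman correlation with a percentile bootstrap confidence interval
#'
#' The point estimate is the Pearson correlation of mid-ranks (average
#' ranks for ties). The CI resamples participants (pairs) with
#' replacement, re-ranks each resample, and takes the percentile interval
#' of the bootstrap distribution.
#'
#' @param a,b Equal-length numeric vectors, one value per participant.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List with `r`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
spearman_with_ci <- function(a, b, n_boot = 2000L, seed = NULL,
                             conf = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 3L, n_boot >= 100L)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be finite")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Spearman correlation undefined for a constant series")
  n <- length(a)
  r <- stats::cor(rank(a), rank(b))
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      ai <- a[idx]; bi <- b[idx]
      if (stats::sd(ai) == 0 || stats::sd(bi) == 0) return(NA_real_)
      stats::cor(rank(ai), rank(bi))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(r = r, ci_low = qs[1], ci_high = qs[2], n = n,
       n_boot = n_boot)
}

#' Bland-Altman limits of agreement
#'
#' Differences are `a - b` (test method minus reference, so systematic
#' over-reporting by the test method gives a positive mean difference).
#' Limits of agreement are the mean difference +/- 2 standard deviations
#' of the differences.
#'
#' @param a,b Equal-length numeric vectors (test and reference method).
#' @param ids Optional participant identifiers for the plot points.
#' @return Object of class `bland_altman`: list with `mean_difference`,
#'   `sd_difference`, `lower_limit`, `upper_limit`, and `points` (data
#'   frame `participant_id`, `mean`, `difference` for plotting).
#' @export
bland_altman <- function(a, b, ids = NULL) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("need at least 2 pairs for limits of agreement")
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  if (is.null(ids)) ids <- seq_along(a)
  structure(
    list(mean_difference = md, sd_difference = sdd,
         lower_limit = md - 2 * sdd, upper_limit = md + 2 * sdd,
         points = data.frame(participant_id = ids, mean = m,
                             difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> mean difference ", round(x$mean_difference, 2),
      ", limits of agreement [", round(x$lower_limit, 2), ", ",
      round(x$upper_limit, 2), "] (+/- 2 SD), n = ", nrow(x$points),
      "\n", sep = "")
  invisible(x)
}

# cut a series at its own quartiles into 4 ordinal classes; values equal
# to a cut fall into the lower quartile
.quartile_classes <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(qs)) < 3L)
    stop("degenerate quartiles: series has too many ties")
  findInterval(x, qs, left.open = TRUE) + 1L
}

#' Weighted kappa on per-method quartiles
#'
#' Each series is cut at its own quartiles into four ordinal classes
#' (values equal to a cut go to the lower quartile); agreement between
#' the two classifications is summarised by the weighted kappa with
#' linear weights `w_ij = 1 - |i-j|/3` (quadratic
#' `w_ij = 1 - ((i-j)/3)^2` available). The p-value is the large-sample
#' normal test of kappa = 0. Also reports the percentage of participants
#' classified into the same, and same-or-adjacent, quartile by the two
#' methods.
#'
#' @param a,b Equal-length numeric vectors.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return List with `kappa`, `p_value`, `se0` (null standard error),
#'   `same_quartile_pct`, `same_or_adjacent_pct`, `table` (the 4x4
#'   contingency table).
#' @export
weighted_kappa_quartiles <- function(a, b,
                                     weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(length(a) == length(b), length(a) >= 8L)
  ca <- .quartile_classes(a)
  cb <- .quartile_classes(b)
  tab <- table(factor(ca, 1:4), factor(cb, 1:4))
  n <- length(a)

  k <- 4L
  d <- abs(outer(1:k, 1:k, "-"))
  w <- if (weights == "linear") 1 - d / (k - 1) else 1 - (d / (k - 1))^2

  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  kappa <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt large-sample variance under kappa = 0
  wr <- as.vector(w %*% pc)        # E[w | row i]
  wc <- as.vector(pr %*% w)        # E[w | col j]
  var0 <- (sum(outer(pr, pc) * (w - outer(wr, wc, "+"))^2) - pe^2) /
    (n * (1 - pe)^2)
  se0 <- sqrt(var0)
  z <- kappa / se0
  p_value <- 2 * stats::pnorm(-abs(z))

  list(kappa = kappa, p_value = p_value, se0 = se0,
       same_quartile_pct = 100 * sum(ca == cb) / n,
       same_or_adjacent_pct = 100 * sum(abs(ca - cb) <= 1L) / n,
       table = tab)
}

#' One-way ANOVA intraclass correlation for two replicates
#'
#' Test-retest reliability as ICC(1,1): participants are random effects,
#' the two replicate measurements are indistinguishable repeats, and
#' `ICC = (MSB - MSW) / (MSB + (k-1) MSW)` with k = 2. The confidence
#' interval is the standard F-based interval.
#'
#' @param first,second Equal-length numeric vectors: the two replicate
#'   measurements per participant.
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `msb`, `msw`, `n`.
#' @export
icc_anova <- function(first, second, conf = 0.95) {
  stopifnot(length(first) == length(second), length(first) >= 3L)
  n <- length(first)
  k <- 2
  m <- cbind(first, second)
  row_means <- rowMeans(m)
  grand <- mean(m)
  if (stats::var(as.vector(m)) == 0)
    stop("zero total variance: ICC undefined")
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)

  alpha <- 1 - conf
  f <- msb / msw
  fl <- f / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci_low = ci[1], ci_high = ci[2],
       msb = msb, msw = msw, n = n)
}

# categories reported on, in display order
.report_categories <- c(sedentary = "sedentary_min", LPA = "lpa_min",
                        `sedentary + LPA` = "sedentary_light_min",
                        MPA = "mpa_min", VPA = "vpa_min",
                        MVPA = "mvpa_min")

.descriptive_row <- function(x) {
  data.frame(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
             min = min(x), max = max(x),
             q25 = unname(stats::quantile(x, 0.25)),
             q75 = unname(stats::quantile(x, 0.75)))
}

#' Assemble the full agreement report for a paired cohort
#'
#' Given per-participant daily-average summaries from the accelerometer
#' (two wear periods) and the questionnaire (two admissions), computes:
#' per-category descriptives for each method/occasion and their average;
#' validity statistics of the first questionnaire admission against the
#' accelerometer two-period average (Spearman + bootstrap CI,
#' Bland-Altman, and weighted kappa for MPA/VPA/MVPA); and test-retest
#' ICCs per method between occasions.
#'
#' @param accel Data frame of accelerometer summaries: `participant_id`,
#'   `period` (1 or 2) and the `daily_summary` columns.
#' @param quest Data frame of questionnaire summaries: `participant_id`,
#'   `admission` (1 or 2) and the same columns.
#' @param n_boot Bootstrap resamples for the Spearman CIs.
#' @param seed Optional seed for the bootstrap.
#' @param categories Named character vector mapping display names to
#'   summary columns; defaults to the six standard categories.
#' @return Object of class `agreement_report`: list of data frames
#'   `descriptives`, `validity`, `reliability`, plus `bland_altman_points`
#'   (one data frame per category).
#' @export
build_report <- function(accel, quest, n_boot = 2000L, seed = NULL,
                         categories = .report_categories) {
  ids <- sort(unique(accel$participant_id))
  for (df_name in c("accel", "quest")) {
    df <- get(df_name)
    for (occ in 1:2) {
      occ_col <- if (df_name == "accel") "period" else "admission"
      have <- df$participant_id[df[[occ_col]] == occ]
      missing <- setdiff(ids, have)
      extra <- setdiff(have, ids)
      if (length(missing) || length(extra))
        stop("participant IDs misaligned in ", df_name, " occasion ", occ,
             ": ", paste(c(missing, extra), collapse = ", "))
    }
  }

  pick <- function(df, occ_col, occ, col) {
    sub <- df[df[[occ_col]] == occ, ]
    sub[[col]][match(ids, sub$participant_id)]
  }

  descriptives <- do.call(rbind, lapply(names(categories), function(cn) {
    col <- categories[[cn]]
    rows <- list(
      `first accelerometer`  = pick(accel, "period", 1, col),
      `second accelerometer` = pick(accel, "period", 2, col),
      `first questionnaire`  = pick(quest, "admission", 1, col),
      `second questionnaire` = pick(quest, "admission", 2, col))
    rows$`average accelerometer` <-
      (rows$`first accelerometer` + rows$`second accelerometer`) / 2
    rows$`average questionnaire` <-
      (rows$`first questionnaire` + rows$`second questionnaire`) / 2
    do.call(rbind, lapply(names(rows), function(m)
      cbind(data.frame(category = cn, series = m), .descriptive_row(rows[[m]]))))
  }))

  kappa_cats <- intersect(c("MPA", "VPA", "MVPA"), names(categories))
  ba_points <- list()
  validity <- do.call(rbind, lapply(names(categories), function(cn) {
    col <- categories[[cn]]
    q1 <- pick(quest, "admission", 1, col)
    acc <- (pick(accel, "period", 1, col) + pick(accel, "period", 2, col)) / 2
    sp <- spearman_with_ci(q1, acc, n_boot = n_boot, seed = seed)
    ba <- bland_altman(q1, acc, ids = ids)
    ba_points[[cn]] <<- ba$points
    row <- data.frame(category = cn, spearman_r = sp$r,
                      ci_low = sp$ci_low, ci_high = sp$ci_high,
                      mean_difference = ba$mean_difference,
                      sd_difference = ba$sd_difference,
                      lower_limit = ba$lower_limit,
                      upper_limit = ba$upper_limit,
                      kappa = NA_real_, kappa_p = NA_real_,
                      same_quartile_pct = NA_real_,
                      same_or_adjacent_pct = NA_real_)
    if (cn %in% kappa_cats) {
      wk <- weighted_kappa_quartiles(q1, acc)
      row$kappa <- wk$kappa
      row$kappa_p <- wk$p_value
      row$same_quartile_pct <- wk$same_quartile_pct
      row$same_or_adjacent_pct <- wk$same_or_adjacent_pct
    }
    row
  }))

  reliability <- do.call(rbind, lapply(names(categories), function(cn) {
    col <- categories[[cn]]
    rbind(
      cbind(data.frame(method = "questionnaire", category = cn),
            as.data.frame(icc_anova(pick(quest, "admission", 1, col),
                                    pick(quest, "admission", 2, col))[
                                      c("icc", "ci_low", "ci_high")])),
      cbind(data.frame(method = "accelerometer", category = cn),
            as.data.frame(icc_anova(pick(accel, "period", 1, col),
                                    pick(accel, "period", 2, col))[
                                      c("icc", "ci_low", "ci_high")])))
  }))

  structure(list(descriptives = descriptives, validity = validity,
                 reliability = reliability,
                 bland_altman_points = ba_points),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n\nValidity (questionnaire vs accelerometer):\n")
  v <- x$validity
  print(data.frame(category = v$category,
                   r = round(v$spearman_r, 2),
                   ci = sprintf("(%.2f-%.2f)", v$ci_low, v$ci_high),
                   mean_diff = round(v$mean_difference, 1),
                   kappa = ifelse(is.na(v$kappa), "", round(v$kappa, 2))),
        row.names = FALSE)
  cat("\nReliability (ICC between occasions):\n")
  r <- x$reliability
  print(data.frame(method = r$method, category = r$category,
                   icc = round(r$icc, 2),
                   ci = sprintf("(%.2f-%.2f)", r$ci_low, r$ci_high)),
        row.names = FALSE)
  invisible(x)
}

#' Write an agreement report's tables to CSV files
#'
#' Writes `descriptives.csv`, `validity.csv`, `reliability.csv` and one
#' `bland_altman_<category>.csv` per category into `dir`.
#'
#' @param report An [build_report()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(report$validity, file.path(dir, "validity.csv"),
                   row.names = FALSE)
  utils::write.csv(report$reliability, file.path(dir, "reliability.csv"),
                   row.names = FALSE)
  for (cn in names(report$bland_altman_points)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", tolower(cn))
    utils::write.csv(report$bland_altman_points[[cn]],
                     file.path(dir, paste0("bland_altman_", safe, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
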