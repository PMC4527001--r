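# Independent oracles: deliberately naive implementations used only to
# check the package's vectorised code paths.

# per-sample loop over each minute: (80/K) * sum |sqrt(x^2+y^2+z^2) - g|
oracle_epochs <- function(x, y, z, k, g = 1) {
  spm <- 60 * k
  n_min <- length(x) %/% spm
  vapply(seq_len(n_min), function(m) {
    s <- 0
    for (j in ((m - 1) * spm + 1):(m * spm))
      s <- s + abs(sqrt(x[j]^2 + y[j]^2 + z[j]^2) - g)
    (80 / k) * s
  }, numeric(1))
}

# textbook closed-form simple OLS
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# weighted kappa from a contingency table by explicit double loops
oracle_weighted_kappa <- function(tab, linear = TRUE) {
  k <- nrow(tab)
  n <- sum(tab)
  po <- pe <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- if (linear) 1 - abs(i - j) / (k - 1) else 1 - ((i - j) / (k - 1))^2
    po <- po + w * tab[i, j] / n
    pe <- pe + w * sum(tab[i, ]) * sum(tab[, j]) / n^2
  }
  (po - pe) / (1 - pe)
}

# one-way ANOVA mean squares by explicit sums, two replicates
oracle_icc <- function(first, second) {
  n <- length(first)
  grand <- mean(c(first, second))
  rm <- (first + second) / 2
  msb <- 2 * sum((rm - grand)^2) / (n - 1)
  msw <- sum((first - rm)^2 + (second - rm)^2) / n
  (msb - msw) / (msb + msw)
}

# quartile classes with ties-to-lower convention, written longhand
oracle_quartiles <- function(x) {
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  vapply(x, function(v) {
    if (v <= qs[1]) 1L else if (v <= qs[2]) 2L
    else if (v <= qs[3]) 3L else 4L
  }, integer(1))
}

# a seeded random raw recording of whole minutes
random_recording <- function(minutes, k = 40, seed = 1,
                             start = "2012-09-03 00:00:00") {
  set.seed(seed)
  n <- minutes * 60 * k
  raw_recording(x = rnorm(n, 0, 0.3), y = rnorm(n, 0, 0.3),
                z = rnorm(n, 1, 0.3), start_time = start, rate_hz = k)
}

# epoch series covering n whole days from `start`, one value per minute
full_series <- function(start, n_days, values = NULL, seed = 1) {
  t0 <- as.POSIXct(start, tz = "UTC")
  n <- n_days * 1440L
  if (is.null(values)) {
    set.seed(seed)
    values <- rexp(n, 1 / 300)
  }
  epoch_series(t0 + 60 * (seq_len(n) - 1), values)
}

printed_model <- function() list(slope = 529, intercept = -627)
printed_cuts <- function() derive_cutpoints(printed_model())
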