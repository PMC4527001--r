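# Raw tri-axial signal -> per-minute SVM_gs epochs.
#
# The wrist device samples acceleration along three axes at K samples/s
# (40 Hz here).  The per-minute summary is the gravity-subtracted signal
# vector magnitude: the sum over the minute's 60*K samples of
# |sqrt(x^2 + y^2 + z^2) - g|, normalised so that recordings made at any
# sampling rate are expressed on a common 80 samples/s reference scale:
#
#   E = (80 / K) * sum_{minute} |sqrt(x^2+y^2+z^2) - g|      [g*min]
#
# At K = 40 this is 2 * sum|magnitude - g|: the per-second mean deviation
# (1/(60K) * sum), times 60 to make a minute epoch, times 2 to rescale a
# 40 Hz recording to the 80 Hz reference.

#' Raw tri-axial accelerometer recording
#'
#' Bundle a contiguous block of tri-axial acceleration samples with its
#' start time, sampling rate and gravity reference. Samples are assumed
#' evenly spaced at `rate_hz`; timestamps are implicit.
#'
#' @param x,y,z Numeric vectors of equal length: acceleration along the
#'   three axes, in g units.
#' @param start_time `POSIXct` scalar (or string parseable as UTC): time of
#'   the first sample.
#' @param rate_hz Integer sampling rate K in samples per second.
#' @param gravity Gravity reference in g units subtracted from the vector
#'   magnitude (default 1.00).
#' @return An object of class `raw_recording`.
#' @examples
#' rec <- raw_recording(x = rep(0, 2400), y = rep(0, 2400),
#'                      z = rep(1, 2400),
#'                      start_time = "2012-09-03 00:00:00", rate_hz = 40)
#' compute_epoch_series(rec)
#' @export
raw_recording <- function(x, y, z, start_time, rate_hz = 40L, gravity = 1.00) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("x, y and z must have equal length")
  rate_hz <- as.integer(rate_hz)
  if (is.na(rate_hz) || rate_hz < 1L)
    stop("rate_hz must be a positive integer")
  bad <- which(!(is.finite(x) & is.finite(y) & is.finite(z)))
  if (length(bad))
    stop("non-finite acceleration sample at index ", bad[1])
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  if (is.na(start_time)) stop("start_time could not be parsed")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         start_time = start_time, rate_hz = rate_hz,
         gravity = as.numeric(gravity)),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  secs <- length(x$x) / x$rate_hz
  cat("<raw_recording> ", length(x$x), " samples @ ", x$rate_hz, " Hz (",
      round(secs / 60, 2), " min) starting ",
      format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      " UTC; g = ", x$gravity, "\n", sep = "")
  invisible(x)
}

# reference rate the epochs are rescaled to (samples/s)
.reference_rate <- 80

#' Compute per-minute SVM_gs epochs from a raw recording
#'
#' Summarises each whole clock minute of the recording into one
#' gravity-subtracted signal vector magnitude value,
#' `(80 / K) * sum(|sqrt(x^2+y^2+z^2) - g|)` over the minute's `60 * K`
#' samples, in g·min on the 80 samples/s reference scale. Epochs are
#' aligned to wall-clock minute boundaries: samples before the first whole
#' minute and after the last whole minute are dropped.
#'
#' @param rec A [raw_recording()].
#' @return An object of class `epoch_series`: a data frame with columns
#'   `epoch_start` (`POSIXct`, UTC, whole minutes) and `svm_gs` (g·min),
#'   with attribute `reference_rate = 80`.
#' @examples
#' # constant 0.1 g deviation for one minute at 40 Hz: 2 * 2400 * 0.1 = 480
#' rec <- raw_recording(rep(0, 2400), rep(0, 2400), rep(1.1, 2400),
#'                      "2012-09-03 10:00:00", rate_hz = 40)
#' compute_epoch_series(rec)$svm_gs
#' @export
compute_epoch_series <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  k <- rec$rate_hz
  spm <- 60L * k  # samples per minute
  n <- length(rec$x)

  # index of the first sample on a whole-minute boundary
  start_num <- as.numeric(rec$start_time)
  offset_sec <- start_num %% 60
  skip <- if (offset_sec == 0) 0L else as.integer(round((60 - offset_sec) * k))
  n_min <- (n - skip) %/% spm
  if (n_min < 1L)
    stop("recording does not cover a whole clock minute")

  idx <- skip + seq_len(n_min * spm)
  dev <- abs(sqrt(rec$x[idx]^2 + rec$y[idx]^2 + rec$z[idx]^2) - rec$gravity)
  sums <- colSums(matrix(dev, nrow = spm))
  svm <- (.reference_rate / k) * sums

  first_min <- start_num + skip / k
  es <- data.frame(
    epoch_start = as.POSIXct(first_min + 60 * (seq_len(n_min) - 1),
                             origin = "1970-01-01", tz = "UTC"),
    svm_gs = svm)
  class(es) <- c("epoch_series", "data.frame")
  attr(es, "reference_rate") <- .reference_rate
  es
}

#' Build an epoch series directly from per-minute values
#'
#' Constructor used by file readers and simulators that already hold
#' minute-level SVM_gs values.
#'
#' @param epoch_start `POSIXct` vector on whole-minute boundaries.
#' @param svm_gs Nonnegative numeric vector, g·min.
#' @return An `epoch_series` data frame.
#' @export
epoch_series <- function(epoch_start, svm_gs) {
  if (!inherits(epoch_start, "POSIXct"))
    epoch_start <- as.POSIXct(epoch_start, tz = "UTC")
  if (length(epoch_start) != length(svm_gs))
    stop("epoch_start and svm_gs must have equal length")
  if (any(!is.finite(svm_gs)) || any(svm_gs < 0))
    stop("svm_gs values must be finite and nonnegative")
  if (any(as.numeric(epoch_start) %% 60 != 0))
    stop("epoch_start values must lie on whole-minute boundaries")
  es <- data.frame(epoch_start = epoch_start, svm_gs = as.numeric(svm_gs))
  class(es) <- c("epoch_series", "data.frame")
  attr(es, "reference_rate") <- .reference_rate
  es
}

#' Extract complete midnight-to-midnight measurement days
#'
#' Returns the first `n_days` complete calendar days of an epoch series,
#' starting at the first midnight at or after the series start. A day is
#' complete iff all 1440 minute epochs are present; participants whose
#' series holds fewer than `n_days` complete days are rejected, mirroring
#' the all-or-nothing inclusion rule of wear-time protocols.
#'
#' @param series An [epoch_series()].
#' @param n_days Number of complete days required (default 6).
#' @return A list of `measurement_day` objects, each with fields `date`
#'   (`Date`), `epochs` (numeric, length 1440) and `complete = TRUE`.
#' @export
extract_complete_days <- function(series, n_days = 6L) {
  stopifnot(inherits(series, "epoch_series"), n_days >= 1L)
  t0 <- as.numeric(series$epoch_start[1])
  midnight0 <- ceiling(t0 / 86400) * 86400
  tnum <- as.numeric(series$epoch_start)

  days <- list()
  d <- 0L
  repeat {
    day_start <- midnight0 + 86400 * d
    wanted <- day_start + 60 * (0:1439)
    pos <- match(wanted, tnum)
    if (anyNA(pos)) break
    days[[length(days) + 1L]] <- structure(
      list(date = as.Date(as.POSIXct(day_start, origin = "1970-01-01",
                                     tz = "UTC")),
           epochs = series$svm_gs[pos],
           complete = TRUE),
      class = "measurement_day")
    d <- d + 1L
    if (length(days) == n_days) break
    if (day_start + 86400 > tnum[length(tnum)]) break
  }
  if (length(days) < n_days)
    stop("only ", length(days), " complete day(s) found, need ", n_days)
  days
}

#' @export
print.measurement_day <- function(x, ...) {
  cat("<measurement_day> ", format(x$date), ": 1440 epochs, mean SVM_gs ",
      round(mean(x$epochs), 1), " g·min\n", sep = "")
  invisible(x)
}

#' Read a raw acceleration CSV
#'
#' Accepts two dialects: (1) `timestamp,x,y,z` with ISO-8601 timestamps
#' (UTC assumed), from which the sampling rate is inferred and checked for
#' regularity; (2) a headerless-timestamp dialect with comment lines
#' `# start_time=<ISO-8601>` and `# rate_hz=<int>` followed by `x,y,z`
#' columns, as written by the simulator.
#'
#' @param path File path.
#' @param gravity Gravity reference passed through to [raw_recording()].
#' @return A [raw_recording()].
#' @export
read_raw_csv <- function(path, gravity = 1.00) {
  head_lines <- readLines(path, n = 10L)
  meta <- grep("^#", head_lines, value = TRUE)
  if (length(meta)) {
    kv <- sub("^#\\s*", "", meta)
    kv <- strsplit(kv, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    start_time <- as.POSIXct(trimws(vals[match("start_time", trimws(keys))]),
                             tz = "UTC")
    rate_hz <- as.integer(vals[match("rate_hz", trimws(keys))])
    dat <- utils::read.csv(path, comment.char = "#")
    return(raw_recording(dat$x, dat$y, dat$z, start_time, rate_hz, gravity))
  }
  dat <- utils::read.csv(path)
  ts <- as.POSIXct(dat$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("unparseable timestamp in ", path)
  dt <- diff(as.numeric(ts))
  rate_hz <- as.integer(round(1 / stats::median(dt)))
  if (any(abs(dt - 1 / rate_hz) > 0.5 / rate_hz))
    stop("timestamps are not regular at the declared/inferred rate of ",
         rate_hz, " Hz")
  raw_recording(dat$x, dat$y, dat$z, ts[1], rate_hz, gravity)
}

#' Write an epoch series to CSV
#'
#' Columns `epoch_start` (ISO-8601 UTC) and `svm_gs`.
#'
#' @param series An [epoch_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  out <- data.frame(
    epoch_start = format(series$epoch_start, "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
    svm_gs = series$svm_gs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch series CSV written by [write_epoch_csv()]
#' @param path File path.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path) {
  dat <- utils::read.csv(path)
  epoch_series(as.POSIXct(dat$epoch_start, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS")),
               dat$svm_gs)
}
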