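# Epoch classification and daily time-in-intensity summaries.
#
# Boundary conventions (shared with the questionnaire scoring): sedentary
# below the MET-1.5 boundary, light below MET 3, moderate from 3 to 6
# inclusive, vigorous strictly above 6.  A complete day always accounts
# for 1440 minutes, before and after the diary-based non-wear correction.

.intensity_levels <- c("sedentary", "LPA", "MPA", "VPA")

#' Classify SVM_gs epochs into intensity categories
#'
#' Vectorised: sedentary if below the sedentary/light boundary, LPA if
#' below the light/moderate boundary, MPA up to and including the
#' moderate/vigorous boundary, VPA above it. The closed moderate band
#' mirrors the MET convention that 3-6 MET is moderate and >6 vigorous.
#'
#' @param svm_gs Nonnegative numeric vector (g·min).
#' @param cuts A [derive_cutpoints()] result.
#' @return Factor with levels `sedentary`, `LPA`, `MPA`, `VPA`.
#' @examples
#' cuts <- derive_cutpoints(list(slope = 529, intercept = -627))
#' classify_epoch(c(105.2, 826.0, 1353.3, 2600), cuts)
#' @export
classify_epoch <- function(svm_gs, cuts) {
  stopifnot(inherits(cuts, "cutpoints"))
  if (any(svm_gs < 0)) stop("svm_gs must be nonnegative")
  b <- unclass(cuts)
  cat_idx <- ifelse(svm_gs < b[1], 1L,
             ifelse(svm_gs < b[2], 2L,
             ifelse(svm_gs <= b[3], 3L, 4L)))
  factor(.intensity_levels[cat_idx], levels = .intensity_levels)
}

#' Classify MET values into intensity categories
#'
#' Sedentary below 1.5 MET, light from 1.5 to below 3, moderate from 3 to
#' 6 inclusive, vigorous above 6. Used for questionnaire items and
#' non-wear diary entries.
#'
#' @param met Positive numeric vector of MET values.
#' @return Factor with levels `sedentary`, `LPA`, `MPA`, `VPA`.
#' @examples
#' classify_met(c(1.3, 1.5, 3, 6, 6.1))
#' @export
classify_met <- function(met) {
  if (any(met <= 0)) stop("MET values must be positive")
  cat_idx <- ifelse(met < 1.5, 1L,
             ifelse(met < 3, 2L,
             ifelse(met <= 6, 3L, 4L)))
  factor(.intensity_levels[cat_idx], levels = .intensity_levels)
}

# internal: build a daily summary row, recomputing the derived categories
.daily_summary <- function(sedentary, lpa, mpa, vpa) {
  d <- data.frame(sedentary_min = sedentary, lpa_min = lpa,
                  mpa_min = mpa, vpa_min = vpa)
  d$sedentary_light_min <- d$sedentary_min + d$lpa_min
  d$mvpa_min <- d$mpa_min + d$vpa_min
  class(d) <- c("daily_summary", "data.frame")
  d
}

#' Summarise one complete day into minutes per intensity category
#'
#' Counts the day's 1440 minute epochs per category; components always sum
#' to 1440. Derived columns `sedentary_light_min` and `mvpa_min` are the
#' usual combined categories.
#'
#' @param day A `measurement_day` from [extract_complete_days()], or a
#'   plain numeric vector of 1440 epochs.
#' @param cuts A [derive_cutpoints()] result.
#' @return One-row data frame of class `daily_summary` with columns
#'   `sedentary_min`, `lpa_min`, `mpa_min`, `vpa_min`,
#'   `sedentary_light_min`, `mvpa_min`.
#' @export
summarize_day <- function(day, cuts) {
  if (inherits(day, "measurement_day")) {
    if (!isTRUE(day$complete)) stop("day is not complete")
    epochs <- day$epochs
  } else epochs <- day
  if (length(epochs) != 1440L)
    stop("a complete day has 1440 epochs, got ", length(epochs))
  counts <- table(classify_epoch(epochs, cuts))
  .daily_summary(counts[["sedentary"]], counts[["LPA"]],
                 counts[["MPA"]], counts[["VPA"]])
}

#' Reassign diary-recorded non-wear time between categories
#'
#' Device-off periods (e.g. swimming) register as sedentary. For every
#' diary entry with MET above 1.5 the entry's duration is moved out of the
#' sedentary category into the category of its MET value; entries at or
#' below 1.5 MET stay within sedentary and are ignored. The 1440-minute
#' total is preserved. If the sedentary category cannot absorb the full
#' subtraction, the remainder is drawn from LPA with a warning (the
#' protocol does not define this degenerate case).
#'
#' @param summary A [summarize_day()] result (or multi-row equivalent; the
#'   correction is applied to the first row).
#' @param entries Data frame with columns `duration_min` and `met`
#'   (column `met_value` is also accepted).
#' @return The corrected `daily_summary`.
#' @examples
#' s <- summarize_day(rep(0, 1440),
#'                    derive_cutpoints(list(slope = 529, intercept = -627)))
#' apply_diary_correction(s, data.frame(duration_min = 30, met = 7))
#' @export
apply_diary_correction <- function(summary, entries) {
  stopifnot(inherits(summary, "daily_summary"))
  if (is.null(entries) || nrow(entries) == 0L) return(summary)
  met <- if ("met" %in% names(entries)) entries$met else entries$met_value
  dur <- entries$duration_min
  if (any(dur <= 0)) stop("diary durations must be positive")
  if (any(dur > 1440)) stop("diary entry longer than a day")
  if (any(met <= 0)) stop("diary MET values must be positive")

  out <- summary[1, ]
  keep <- met > 1.5
  if (!any(keep)) return(out)
  cats <- classify_met(met[keep])
  add <- tapply(dur[keep], cats, sum, default = 0)

  total_move <- sum(add)
  from_sed <- min(out$sedentary_min, total_move)
  deficit <- total_move - from_sed
  out$sedentary_min <- out$sedentary_min - from_sed
  if (deficit > 0) {
    warning("diary correction exceeds sedentary time; drawing ",
            round(deficit, 1), " min from LPA")
    out$lpa_min <- out$lpa_min - deficit
    if (out$lpa_min < 0) stop("diary correction exceeds sedentary + LPA time")
  }
  out$lpa_min <- out$lpa_min + add[["LPA"]]
  out$mpa_min <- out$mpa_min + add[["MPA"]]
  out$vpa_min <- out$vpa_min + add[["VPA"]]
  .daily_summary(out$sedentary_min, out$lpa_min, out$mpa_min, out$vpa_min)
}

#' Average daily summaries over measurement days
#'
#' Arithmetic mean per category across all supplied days (e.g. the 12
#' days of two 6-day wear periods), weighting every day equally. Derived
#' columns are recomputed from the averaged components.
#'
#' @param summaries A list of `daily_summary` rows, or a data frame whose
#'   rows are daily summaries.
#' @return One-row `daily_summary`.
#' @export
average_periods <- function(summaries) {
  if (inherits(summaries, "daily_summary") || is.data.frame(summaries)) {
    df <- as.data.frame(summaries)
  } else {
    if (length(summaries) == 0L) stop("no summaries to average")
    df <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  if (nrow(df) == 0L) stop("no summaries to average")
  .daily_summary(mean(df$sedentary_min), mean(df$lpa_min),
                 mean(df$mpa_min), mean(df$vpa_min))
}

#' Read a non-wear diary CSV (`date,duration_min,activity,met`)
#' @param path File path.
#' @return Data frame with a `Date`-typed `date` column.
#' @export
read_diary_csv <- function(path) {
  dat <- utils::read.csv(path)
  dat$date <- as.Date(dat$date)
  dat
}

#' Write per-participant daily summaries to CSV
#'
#' @param summaries Data frame with `participant_id`, `period` and the
#'   `daily_summary` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
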