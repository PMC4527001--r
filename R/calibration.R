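# MET -> SVM_gs calibration.
#
# Steady-state activity bouts with known MET cost (sitting, standing,
# walking at set speeds) give paired (MET, SVM_gs) observations; ordinary
# least squares of SVM_gs on MET gives a study-specific line whose values
# at MET 1.5, 3 and 6 are the intensity cut points.

#' Steady-state SVM_gs of a calibration bout
#'
#' Extracts the mean of the middle three minute epochs of a bout, dropping
#' the first and last minutes to avoid transition artefacts (for the
#' standard 5-minute bout: epochs 2-4).
#'
#' @param bout_epochs Numeric vector of consecutive minute epochs, or an
#'   [epoch_series()].
#' @param bout_minutes Length of the bout; defaults to the number of
#'   epochs supplied. Must be at least 3.
#' @return Scalar mean SVM_gs (g·min) of the middle three minutes.
#' @examples
#' extract_steady_state(c(100, 110, 120, 130, 140))  # 120
#' @export
extract_steady_state <- function(bout_epochs, bout_minutes = NULL) {
  if (inherits(bout_epochs, "epoch_series")) bout_epochs <- bout_epochs$svm_gs
  if (is.null(bout_minutes)) bout_minutes <- length(bout_epochs)
  if (length(bout_epochs) != bout_minutes)
    stop("bout_epochs holds ", length(bout_epochs), " epochs, expected ",
         bout_minutes)
  if (bout_minutes < 3L)
    stop("bout must be at least 3 minutes long")
  # centre the 3-minute window; for a 5-minute bout this is epochs 2:4
  take <- seq.int(floor((bout_minutes - 3) / 2) + 1L, length.out = 3L)
  mean(bout_epochs[take])
}

#' Fit the linear MET calibration
#'
#' Ordinary least squares of observed steady-state SVM_gs (g·min) on the
#' activities' MET values. With a balanced design (every activity measured
#' on every device) fitting per-activity means gives the same line as
#' fitting all individual observations.
#'
#' @param obs Data frame with columns `met` and `svm_gs` (extra columns
#'   such as `participant_id`, `activity` are ignored).
#' @return Object of class `calibration_model` with fields `slope`
#'   (g·min per MET), `intercept` (g·min) and `n_points`.
#' @examples
#' fit_calibration(genea_calibration_means())
#' @export
fit_calibration <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("met", "svm_gs") %in% names(obs)))
  met <- as.numeric(obs$met)
  svm <- as.numeric(obs$svm_gs)
  if (any(!is.finite(met)) || any(!is.finite(svm)))
    stop("non-finite calibration observation")
  if (any(met <= 0)) stop("MET values must be positive")
  if (any(svm < 0)) stop("svm_gs values must be nonnegative")
  if (length(unique(met)) < 2L)
    stop("need at least 2 distinct MET levels to fit a slope")
  fit <- stats::lm(svm ~ met)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n_points = length(met)),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> SVM_gs = ", format(round(x$slope, 2)),
      " x MET ", ifelse(x$intercept < 0, "- ", "+ "),
      format(abs(round(x$intercept, 2))),
      "  (n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Intensity cut points from a calibration model
#'
#' Evaluates the fitted line at the MET thresholds separating sedentary
#' (<1.5 MET), light (<3), moderate (3-6) and vigorous (>6) activity.
#' Negative values clamp to 0 because SVM_gs cannot be negative.
#'
#' @param model A [fit_calibration()] result, or a list with `slope` and
#'   `intercept`.
#' @param met_thresholds Ascending MET thresholds (default `c(1.5, 3, 6)`).
#' @return Object of class `cutpoints`: named numeric vector
#'   `sedentary_light`, `light_moderate`, `moderate_vigorous` (g·min),
#'   with the thresholds kept as attribute `met_thresholds`.
#' @examples
#' derive_cutpoints(list(slope = 529, intercept = -627))
#' @export
derive_cutpoints <- function(model, met_thresholds = c(1.5, 3, 6)) {
  stopifnot(length(met_thresholds) == 3L,
            !is.unsorted(met_thresholds, strictly = TRUE))
  if (!is.finite(model$slope) || model$slope <= 0)
    stop("calibration slope must be positive to derive cut points")
  b <- pmax(0, model$slope * met_thresholds + model$intercept)
  if (is.unsorted(b, strictly = TRUE))
    stop("derived boundaries are not strictly increasing (clamping ",
         "collapsed the lower cut points)")
  structure(stats::setNames(b, c("sedentary_light", "light_moderate",
                                 "moderate_vigorous")),
            met_thresholds = met_thresholds,
            class = "cutpoints")
}

#' @export
print.cutpoints <- function(x, ...) {
  cat("<cutpoints> g·min at MET ",
      paste(attr(x, "met_thresholds"), collapse = "/"), ": ",
      paste(format(round(unclass(x), 1)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Calibration-study activity means
#'
#' Per-activity mean steady-state SVM_gs (g·min) of the five calibration
#' activities — sitting, standing and treadmill walking at 3.2, 4.8 and
#' 6.4 km/h — averaged over 44 wrist devices, with the activities'
#' compendium MET values. Fitting this table reproduces the study line
#' SVM_gs = 529 x MET - 627.
#'
#' @return Data frame with columns `activity`, `met`, `svm_gs`, `svm_gs_sd`.
#' @export
genea_calibration_means <- function() {
  data.frame(
    activity = c("sitting", "standing", "walking_3.2_kmh",
                 "walking_4.8_kmh", "walking_6.4_kmh"),
    met = c(1.5, 1.8, 2.5, 3.3, 5.0),
    svm_gs = c(105.2, 167.1, 826.0, 1353.3, 1875.3),
    svm_gs_sd = c(77.5, 146.3, 236.1, 246.2, 438.4))
}

#' Read calibration observations from CSV
#'
#' Expects columns `participant_id,activity,met,svm_gs`.
#'
#' @param path File path.
#' @return Data frame suitable for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("met", "svm_gs")
  if (!all(need %in% names(dat)))
    stop("calibration CSV must have columns met and svm_gs")
  dat
}

#' Write a calibration model and its cut points as key=value text
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @param cuts Optional [derive_cutpoints()] result to append.
#' @return `path`, invisibly.
#' @export
write_calibration_model <- function(model, path, cuts = NULL) {
  lines <- c(sprintf("slope=%.10g", model$slope),
             sprintf("intercept=%.10g", model$intercept),
             sprintf("n_points=%d", model$n_points))
  if (!is.null(cuts)) {
    thr <- attr(cuts, "met_thresholds")
    lines <- c(lines, sprintf("cut_%s=%.10g",
                              gsub("\\.", "_", format(thr)), unclass(cuts)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a key=value calibration model file
#' @param path File path written by [write_calibration_model()].
#' @return A `calibration_model`.
#' @export
read_calibration_model <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  structure(list(slope = as.numeric(vals[["slope"]]),
                 intercept = as.numeric(vals[["intercept"]]),
                 n_points = as.integer(vals[["n_points"]])),
            class = "calibration_model")
}
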