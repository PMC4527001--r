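# Synthetic cohorts for exercising the full pipeline.
#
# Two generators:
#
#  * generate_raw_day(): a raw tri-axial signal whose per-minute SVM_gs
#    epochs average to the calibration line's value for each scheduled
#    activity, for round-trip testing of the signal pipeline.
#
#  * generate_paired_cohort(): per-participant daily-average intensity
#    summaries for two accelerometer wear periods and two questionnaire
#    admissions, with controllable between-method Spearman correlation,
#    within-method test-retest ICC, and multiplicative over-reporting of
#    moderate/vigorous time by the questionnaire.
#
# Cohort construction: each participant carries a latent activity
# propensity per component (moderate time, vigorous time, sedentary share
# of non-MVPA time). Observed values are shifted-lognormal (or
# logit-normal for the share) transforms of a one-way random-effects
# Gaussian latent, so
#   - the between-method rank correlation is set exactly through a
#     Gaussian copula (Spearman = (6/pi) asin(rho/2) for bivariate
#     normals), with the copula parameter solved in closed form after
#     accounting for attenuation by within-method occasion noise;
#   - the within-method ICC on the observed lognormal scale is set
#     exactly by solving the latent replicate correlation rho* from
#     ICC_obs = (exp(rho* s^2) - 1) / (exp(s^2) - 1).
# Moderate and vigorous minutes are drawn directly; the sedentary/light
# block is the 1440-minute remainder, split by the method-specific
# sedentary share, so every record satisfies the 1440-minute budget by
# construction.

#' Specification of a synthetic validation cohort
#'
#' Defaults emulate a cohort of 148 men wearing a wrist accelerometer for
#' two 6-day periods and answering the questionnaire twice, with
#' accelerometer-scale moderate/vigorous time distributions and
#' questionnaire over-reporting matching a typical validation study:
#' accelerometer MPA 46 (SD 27) and VPA 3 (SD 6) min/day, questionnaire
#' means larger by factors 2.6 (MPA) and 6.5 (VPA), between-method
#' Spearman targets 0.19/0.27/0.54 (sedentary share/MPA/VPA) and
#' test-retest ICC targets 0.78 (accelerometer) and 0.67 (questionnaire).
#'
#' @param n_participants Cohort size (>= 3).
#' @param days_per_period Complete accelerometer days per wear period.
#' @param periods Number of wear periods.
#' @param admissions Number of questionnaire admissions.
#' @param target_spearman Named numeric: target Spearman between the first
#'   questionnaire admission and the accelerometer all-period average, for
#'   the directly generated components `sedentary` (the sedentary-share
#'   latent), `mpa` and `vpa`. Derived categories (LPA, MVPA, combined
#'   sedentary+LPA) inherit emergent correlations.
#' @param target_icc_accelerometer,target_icc_questionnaire Target
#'   test-retest ICC between occasions, on the observed scale, applied to
#'   each directly generated component.
#' @param overreport_factor_mpa,overreport_factor_vpa Multiplicative
#'   questionnaire over-reporting of moderate and vigorous time (> 0; 1 =
#'   unbiased).
#' @param accel_mpa_mean,accel_mpa_sd,accel_mpa_shift Accelerometer MPA
#'   min/day: mean, SD and lower shift of the shifted-lognormal scale.
#' @param accel_vpa_mean,accel_vpa_sd,accel_vpa_shift Same for VPA.
#' @param sed_share_accel,sed_share_quest,sed_share_sd Mean sedentary
#'   share of non-MVPA time per method, and its between-participant SD.
#' @param seed Integer seed; identical spec + seed give identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 148L,
                        days_per_period = 6L,
                        periods = 2L,
                        admissions = 2L,
                        target_spearman = c(sedentary = 0.19, mpa = 0.27,
                                            vpa = 0.54),
                        target_icc_accelerometer = 0.78,
                        target_icc_questionnaire = 0.67,
                        overreport_factor_mpa = 2.6,
                        overreport_factor_vpa = 6.5,
                        accel_mpa_mean = 46, accel_mpa_sd = 27,
                        accel_mpa_shift = 3,
                        accel_vpa_mean = 3, accel_vpa_sd = 6,
                        accel_vpa_shift = 0,
                        sed_share_accel = 0.567,
                        sed_share_quest = 0.466,
                        sed_share_sd = 0.13,
                        seed = NULL) {
  spec <- as.list(environment())
  if (spec$n_participants < 3L) stop("need at least 3 participants")
  ts <- spec$target_spearman
  if (!all(c("sedentary", "mpa", "vpa") %in% names(ts)))
    stop("target_spearman must name sedentary, mpa and vpa")
  if (any(ts < 0 | ts > 1)) stop("target Spearman values must be in [0, 1]")
  for (icc in c(spec$target_icc_accelerometer,
                spec$target_icc_questionnaire))
    if (icc <= 0 || icc > 1) stop("target ICCs must be in (0, 1]")
  if (spec$overreport_factor_mpa <= 0 || spec$overreport_factor_vpa <= 0)
    stop("over-reporting factors must be positive")
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n = ", x$n_participants, ", ", x$periods,
      " wear periods x ", x$days_per_period, " days, ", x$admissions,
      " questionnaire admissions\n",
      "  target Spearman: ",
      paste(names(x$target_spearman), round(x$target_spearman, 2),
            sep = "=", collapse = ", "), "\n",
      "  target ICC: accelerometer ", x$target_icc_accelerometer,
      ", questionnaire ", x$target_icc_questionnaire, "\n",
      "  over-reporting: MPA x", x$overreport_factor_mpa,
      ", VPA x", x$overreport_factor_vpa, "\n", sep = "")
  invisible(x)
}

# shifted-lognormal parameters from mean/sd/shift
.lnorm_pars <- function(mean, sd, shift) {
  m <- mean - shift
  if (m <= 0) stop("lognormal mean must exceed the shift")
  s2 <- log(1 + (sd / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2), shift = shift)
}

# latent replicate correlation giving target ICC on the observed
# (shifted-lognormal) scale
.latent_icc <- function(icc, sdlog) {
  e <- expm1(sdlog^2)
  log1p(icc * e) / sdlog^2
}

# copula parameter between the questionnaire person effect and the
# accelerometer person effect that yields the target Spearman between one
# questionnaire admission and the accelerometer average over `periods`
# occasions, both observed through monotone transforms of their latents
.copula_param <- function(rho_s, rho_a, rho_q, periods) {
  c_target <- 2 * sin(pi * rho_s / 6)
  vbar <- rho_a + (1 - rho_a) / periods
  r <- c_target * sqrt(vbar) / sqrt(rho_a * rho_q)
  if (r > 1) {
    warning("target Spearman ", round(rho_s, 2),
            " is unattainable at the requested ICCs; using the maximum")
    r <- 1
  }
  r
}

# one-way random-effects latents: n x occasions matrix with replicate
# correlation rho, person effect given
.occasion_latents <- function(person, rho, occasions) {
  n <- length(person)
  noise <- matrix(stats::rnorm(n * occasions), n, occasions)
  sqrt(rho) * person + sqrt(1 - rho) * noise
}

#' Generate a paired synthetic cohort
#'
#' Draws per-participant daily-average intensity summaries for both
#' accelerometer wear periods and both questionnaire admissions under the
#' latent-propensity model described in [cohort_spec()]. Every generated
#' record satisfies the 1440 minutes/day budget; generation is a pure
#' function of the spec and its seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `accelerometer` (data frame:
#'   `participant_id`, `period`, category minutes) and `questionnaire`
#'   (`participant_id`, `admission`, category minutes, `total_met_h_24`),
#'   plus the `spec`.
#' @export
generate_paired_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_participants
    pe <- spec$periods
    ad <- spec$admissions

    mpa_a <- .lnorm_pars(spec$accel_mpa_mean, spec$accel_mpa_sd,
                         spec$accel_mpa_shift)
    vpa_a <- .lnorm_pars(spec$accel_vpa_mean, spec$accel_vpa_sd,
                         spec$accel_vpa_shift)
    # questionnaire scale: mean, SD and shift all multiplied by the
    # over-reporting factor (coefficient of variation preserved)
    fm <- spec$overreport_factor_mpa
    fv <- spec$overreport_factor_vpa

    comp <- list(
      mpa = list(pars = mpa_a, factor = fm,
                 rho_s = spec$target_spearman[["mpa"]]),
      vpa = list(pars = vpa_a, factor = fv,
                 rho_s = spec$target_spearman[["vpa"]]))

    draw <- function(cm) {
      sdlog <- cm$pars$sdlog
      rho_a <- .latent_icc(spec$target_icc_accelerometer, sdlog)
      rho_q <- .latent_icc(spec$target_icc_questionnaire, sdlog)
      r <- .copula_param(cm$rho_s, rho_a, rho_q, pe)
      person_a <- stats::rnorm(n)
      person_q <- r * person_a + sqrt(1 - r^2) * stats::rnorm(n)
      la <- .occasion_latents(person_a, rho_a, pe)
      lq <- .occasion_latents(person_q, rho_q, ad)
      list(accel = cm$pars$shift +
             exp(cm$pars$meanlog + sdlog * la),
           quest = cm$factor *
             (cm$pars$shift + exp(cm$pars$meanlog + sdlog * lq)))
    }

    mpa <- draw(comp$mpa)
    vpa <- draw(comp$vpa)

    # sedentary share of the non-MVPA block: logit-normal, latent ICC
    # taken directly at the target (the logistic transform is close to
    # linear over the bulk of the share distribution)
    tau_a <- spec$sed_share_sd /
      (spec$sed_share_accel * (1 - spec$sed_share_accel))
    tau_q <- spec$sed_share_sd /
      (spec$sed_share_quest * (1 - spec$sed_share_quest))
    rho_a <- spec$target_icc_accelerometer
    rho_q <- spec$target_icc_questionnaire
    r_s <- .copula_param(spec$target_spearman[["sedentary"]],
                         rho_a, rho_q, pe)
    person_a <- stats::rnorm(n)
    person_q <- r_s * person_a + sqrt(1 - r_s^2) * stats::rnorm(n)
    share_a <- stats::plogis(stats::qlogis(spec$sed_share_accel) +
                               tau_a * .occasion_latents(person_a, rho_a, pe))
    share_q <- stats::plogis(stats::qlogis(spec$sed_share_quest) +
                               tau_q * .occasion_latents(person_q, rho_q, ad))

    assemble <- function(mpa_m, vpa_m, share_m, occ_name, occasions) {
      out <- do.call(rbind, lapply(seq_len(occasions), function(t) {
        mpa_t <- mpa_m[, t]
        vpa_t <- vpa_m[, t]
        mvpa <- mpa_t + vpa_t
        over <- mvpa > 1435
        if (any(over)) {  # defensive: keep the non-MVPA block positive
          scl <- 1435 / mvpa[over]
          mpa_t[over] <- mpa_t[over] * scl
          vpa_t[over] <- vpa_t[over] * scl
          mvpa[over] <- 1435
        }
        rest <- 1440 - mvpa
        sed <- share_m[, t] * rest
        d <- .daily_summary(sed, rest - sed, mpa_t, vpa_t)
        cbind(data.frame(participant_id = seq_len(n)),
              stats::setNames(data.frame(t), occ_name), d)
      }))
      class(out) <- c("daily_summary", "data.frame")
      out
    }

    accel <- assemble(mpa$accel, vpa$accel, share_a, "period", pe)
    quest <- assemble(mpa$quest, vpa$quest, share_q, "admission", ad)
    # 24-h-consistent total MET-h at representative category intensities
    quest$total_met_h_24 <- (quest$sedentary_min * 1.3 +
                               quest$lpa_min * 2.3 +
                               quest$mpa_min * 4.0 +
                               quest$vpa_min * 7.5) / 60

    list(accelerometer = accel, questionnaire = quest, spec = spec)
  })
}

#' Daily activity schedule for the raw-signal generator
#'
#' Builds a non-overlapping schedule of (start, duration, MET) entries.
#' `constant_schedule()` is the single-activity whole-day special case.
#'
#' @param start_minute,duration_min,met Equal-length vectors; starts in
#'   minutes from midnight.
#' @return Data frame of class `day_schedule`.
#' @export
day_schedule <- function(start_minute, duration_min, met) {
  s <- data.frame(start_minute = as.integer(start_minute),
                  duration_min = as.integer(duration_min),
                  met = as.numeric(met))
  s <- s[order(s$start_minute), ]
  ends <- s$start_minute + s$duration_min
  if (any(s$start_minute[-1] < ends[-nrow(s)]))
    stop("schedule entries overlap")
  if (any(s$start_minute[-1] != ends[-nrow(s)]))
    stop("schedule has gaps")
  if (any(s$met <= 0)) stop("MET values must be positive")
  class(s) <- c("day_schedule", "data.frame")
  s
}

#' @rdname day_schedule
#' @param duration_total Total schedule length in minutes (default 1440).
#' @export
constant_schedule <- function(met, duration_total = 1440L) {
  day_schedule(0L, duration_total, met)
}

#' Generate a raw tri-axial recording for a scheduled day
#'
#' Inverts the calibration line: for each scheduled activity the expected
#' minute epoch is `max(0, slope * MET + intercept)` g·min, so the mean
#' per-sample deviation from gravity is that value divided by
#' `60 * 80` (the epoch formula's reference normalisation, independent of
#' the recording rate). Per-sample deviation magnitudes are drawn from a
#' gamma distribution with that mean (shape `noise_shape`; `Inf` gives a
#' noiseless constant deviation), a random sign is applied where it keeps
#' the magnitude nonnegative, and orientation is uniform on the sphere.
#' Re-processing the recording with [compute_epoch_series()] recovers the
#' scheduled epoch values up to sampling noise.
#'
#' @param schedule A [day_schedule()] starting at minute 0.
#' @param model Calibration model (`slope`, `intercept`).
#' @param start_time Start of the recording (default midnight 2012-09-03).
#' @param rate_hz Sampling rate K (default 40).
#' @param noise_shape Gamma shape of the per-sample deviation
#'   distribution; larger is less noisy (default 4).
#' @param gravity Gravity reference (default 1.00).
#' @param seed Optional integer seed.
#' @return A [raw_recording()] covering the schedule.
#' @export
generate_raw_day <- function(schedule, model,
                             start_time = as.POSIXct("2012-09-03 00:00:00",
                                                     tz = "UTC"),
                             rate_hz = 40L, noise_shape = 4,
                             gravity = 1.00, seed = NULL) {
  stopifnot(inherits(schedule, "day_schedule"))
  if (schedule$start_minute[1] != 0L)
    stop("schedule must start at minute 0")
  if (!is.finite(model$slope) || model$slope <= 0)
    stop("calibration slope must be positive")
  .with_seed(seed, {
    k <- as.integer(rate_hz)
    targets <- model$slope * schedule$met + model$intercept
    clamped <- targets < 0
    if (any(clamped)) {
      warning("expected SVM_gs negative for MET ",
              paste(schedule$met[clamped], collapse = ", "),
              "; clamping to 0")
      targets[clamped] <- 0
    }
    # mean per-sample deviation: E = (80/K) * 60K * d  =>  d = E / 4800
    dev_mean <- rep(targets / (60 * .reference_rate),
                    schedule$duration_min * 60L * k)
    nsamp <- length(dev_mean)
    dev <- if (is.finite(noise_shape)) {
      ifelse(dev_mean > 0,
             stats::rgamma(nsamp, shape = noise_shape,
                           rate = noise_shape) * dev_mean,
             0)
    } else dev_mean
    sign <- ifelse(dev <= gravity & stats::runif(nsamp) < 0.5, -1, 1)
    mag <- gravity + sign * dev
    u <- matrix(stats::rnorm(3 * nsamp), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    raw_recording(mag * u[, 1], mag * u[, 2], mag * u[, 3],
                  start_time, k, gravity)
  })
}

#' Simulate steady-state calibration bouts for a device cohort
#'
#' For each participant and activity, draws a 5-minute bout of minute
#' epochs around the calibration line's expected value with multiplicative
#' device noise, and extracts the steady-state mean — the raw material
#' for [fit_calibration()].
#'
#' @param model True calibration model generating the data.
#' @param activities Data frame with `activity` and `met` columns
#'   (default: the five-activity protocol of [genea_calibration_means()]).
#' @param n_participants Number of devices/participants.
#' @param cv Multiplicative noise coefficient of variation per epoch.
#' @param seed Optional integer seed.
#' @return Data frame `participant_id`, `activity`, `met`, `svm_gs`.
#' @export
generate_calibration_bouts <- function(model,
                                       activities =
                                         genea_calibration_means()[1:2],
                                       n_participants = 22L,
                                       cv = 0.15, seed = NULL) {
  .with_seed(seed, {
    grid <- expand.grid(participant_id = seq_len(n_participants),
                        idx = seq_len(nrow(activities)))
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      row <- activities[grid$idx[i], ]
      expect <- max(0, model$slope * row$met + model$intercept)
      bout <- expect * (1 + cv * stats::rnorm(5))
      bout <- pmax(bout, 0)
      data.frame(participant_id = grid$participant_id[i],
                 activity = row$activity, met = row$met,
                 svm_gs = extract_steady_state(bout))
    }))
    out
  })
}
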