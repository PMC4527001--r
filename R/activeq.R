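# Questionnaire scoring.
#
# Each questionnaire item (occupation level, transportation mode, leisure
# or sporting activity, sleep) carries a compendium MET value. Reported
# hours/day accumulate into intensity categories by the item's MET, and a
# 24-hour-adjusted total MET-h fills (or trims) the gap between the
# reported total and 24 h at MET 2.0 — the assumed average intensity of
# unreported time (between sitting/eating at 1.5 and light home activity
# at 2.5).

#' Default activity-to-MET catalogue
#'
#' A representative catalogue covering the activity domains of a
#' habitual-activity questionnaire: daily occupation (four activity
#' levels), transportation, leisure-time activities, sports and sleep.
#' MET values are representative compendium values; the classification
#' boundaries (1.5, 3, 6), not the individual item values, are the fixed
#' convention.
#'
#' @return Data frame with columns `item_id`, `label`, `domain`, `met`.
#' @export
default_met_catalogue <- function() {
  data.frame(
    item_id = c("work_sedentary", "work_light", "work_moderate",
                "work_heavy",
                "transport_walk", "transport_bicycle", "transport_car",
                "walking_leisure", "household_work", "gardening", "yoga",
                "swimming", "bicycling", "spinning", "skiing", "squash",
                "running", "sitting_leisure", "sleep"),
    label = c("sedentary work", "light work", "moderate work",
              "heavy manual work",
              "walking to work", "bicycling to work", "driving to work",
              "leisure walking", "household work", "gardening", "yoga",
              "swimming laps", "bicycling", "spinning class",
              "cross-country skiing", "squash", "running",
              "sitting during leisure", "sleep"),
    domain = c(rep("daily occupation", 4), rep("transportation", 3),
               rep("leisure", 4), rep("sport", 6), "leisure", "sleep"),
    met = c(1.3, 2.0, 3.5, 6.5,
            3.5, 6.8, 1.3,
            3.0, 2.8, 3.8, 2.5,
            7.0, 7.5, 8.5, 9.0, 9.5, 8.0,
            1.3, 0.95))
}

#' Score one questionnaire response
#'
#' Accumulates reported hours/day into intensity categories by each
#' item's MET value (using the shared MET boundaries, see
#' [classify_met()]) and computes the 24-hour-adjusted total MET-h:
#' `sum(hours * MET) + (24 - sum(hours)) * fill_met`. Hours missing from
#' 24 are added — and over-reported hours subtracted — at `fill_met`
#' (default 2.0).
#'
#' @param resp Data frame with columns `item_id` and `hours_per_day`
#'   (repeated `item_id`s are summed). Optional columns `participant_id`,
#'   `admission` are carried through.
#' @param catalogue Activity catalogue data frame with `item_id` and
#'   `met` columns; defaults to [default_met_catalogue()].
#' @param fill_met MET value of the time added/subtracted in the 24-h
#'   adjustment.
#' @return One-row data frame of class `questionnaire_summary`: category
#'   minutes (`sedentary_min`, `lpa_min`, `mpa_min`, `vpa_min`, derived
#'   `sedentary_light_min`, `mvpa_min`) plus `total_met_h_24`.
#' @examples
#' resp <- data.frame(item_id = c("running", "sleep", "sitting_leisure"),
#'                    hours_per_day = c(1, 8, 15))
#' score_response(resp)
#' @export
score_response <- function(resp, catalogue = default_met_catalogue(),
                           fill_met = 2.0) {
  stopifnot(all(c("item_id", "hours_per_day") %in% names(resp)))
  if (any(resp$hours_per_day < 0)) stop("hours_per_day must be nonnegative")
  pos <- match(resp$item_id, catalogue$item_id)
  if (anyNA(pos))
    stop("unknown item_id: ",
         paste(unique(resp$item_id[is.na(pos)]), collapse = ", "))
  met <- catalogue$met[pos]
  hours <- resp$hours_per_day
  cats <- classify_met(met)
  mins <- tapply(hours * 60, cats, sum, default = 0)

  total_hours <- sum(hours)
  fill_hours <- 24 - total_hours
  total_met_h <- sum(hours * met) + fill_hours * fill_met

  out <- .daily_summary(mins[["sedentary"]], mins[["LPA"]],
                        mins[["MPA"]], mins[["VPA"]])
  out$total_met_h_24 <- total_met_h
  if (!is.null(resp$participant_id))
    out <- cbind(participant_id = resp$participant_id[1], out)
  if (!is.null(resp$admission))
    out <- cbind(out, admission = resp$admission[1])
  class(out) <- c("questionnaire_summary", "daily_summary", "data.frame")
  out
}

#' Restrict catalogue items to those a respondent is asked about
#'
#' Screening questions determine which activities are followed up:
#' respondents not working skip the occupation and transportation items;
#' leisure and sport items appear only if selected in the screening; the
#' sleep question is always asked.
#'
#' @param screened Character vector of item_ids ticked in the screening
#'   questions.
#' @param working Logical: does the respondent work?
#' @param catalogue Activity catalogue (default [default_met_catalogue()]).
#' @return Character vector of item_ids the respondent is asked about, in
#'   catalogue order.
#' @export
follow_up_filter <- function(screened, working,
                             catalogue = default_met_catalogue()) {
  keep <- vapply(seq_len(nrow(catalogue)), function(i) {
    dom <- catalogue$domain[i]
    id <- catalogue$item_id[i]
    if (dom == "sleep") return(TRUE)
    if (dom %in% c("daily occupation", "transportation"))
      return(isTRUE(working) && id %in% screened)
    id %in% screened
  }, logical(1))
  catalogue$item_id[keep]
}

#' Read questionnaire responses from CSV
#'
#' Expects `participant_id,admission,item_id,hours_per_day`; returns one
#' data frame per participant-admission in a named list.
#'
#' @param path File path.
#' @return List of response data frames, named `<participant>_<admission>`.
#' @export
read_response_csv <- function(path) {
  dat <- utils::read.csv(path)
  split(dat, interaction(dat$participant_id, dat$admission, sep = "_",
                         drop = TRUE))
}

#' Read an activity catalogue CSV (`item_id,label,domain,met`)
#' @param path File path.
#' @return Catalogue data frame.
#' @export
read_catalogue_csv <- function(path) {
  dat <- utils::read.csv(path)
  if (!all(c("item_id", "met") %in% names(dat)))
    stop("catalogue CSV must have item_id and met columns")
  dat
}
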