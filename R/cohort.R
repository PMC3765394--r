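# Cohort construction: index-date identification and temporal windowing.
# All windows are anchored to the index date (first RA diagnostic code):
# analysis window = [index - 365, index + 14]; the keyword search window may
# extend earlier, back to the first DMARD prescription or first specific
# marker code.

#' Effective date of an event
#'
#' The event date when entered; otherwise the date the record was created
#' (the system date), which is always present.
#'
#' @param events Events data.frame ([read_events()]).
#' @return `Date` vector, one per event.
#' @export
effective_date <- function(events) {
  if (anyNA(events$system_date)) stop("system_date must be present")
  d <- events$event_date
  miss <- is.na(d)
  d[miss] <- events$system_date[miss]
  d
}

#' Valid observation bounds per patient
#'
#' Observation starts at the later of the registration date and the practice
#' up-to-standard date, and ends at the earlier of transfer-out (when
#' present) and the last data collection. Patients whose start postdates
#' their end are flagged unusable.
#'
#' @param patients Patients data.frame ([read_patients()]).
#' @return Data.frame with `patient_id`, `obs_start`, `obs_end`, `usable`.
#' @export
observation_bounds <- function(patients) {
  start <- pmax(patients$registration_date, patients$uts_date)
  end <- patients$last_collection_date
  has_transfer <- !is.na(patients$transfer_out_date)
  end[has_transfer] <- pmin(end[has_transfer],
                            patients$transfer_out_date[has_transfer])
  data.frame(patient_id = patients$patient_id,
             obs_start = start, obs_end = end,
             usable = start <= end, stringsAsFactors = FALSE)
}

#' Identify incident RA cases
#'
#' A patient enters the cohort iff their first RA diagnostic code (by
#' effective date) falls inside the study period, no RA code predates the
#' study start, they are aged 30 or over at index (age = index year minus
#' year of birth), and their observation bounds cover the full window from
#' one year before to 14 days after the index code.
#'
#' @param patients,events Data.frames ([read_patients()], [read_events()]).
#' @param ra_codes [code_spec()] of RA diagnostic codes.
#' @param study_start,study_end Study period bounds (`Date`).
#' @return Cohort data.frame (one row per included patient: `patient_id`,
#'   `gender`, `year_of_birth`, `index_date`, `age_at_index`, `window_start`,
#'   `window_end`, `obs_start`, `obs_end`) with an `exclusions` attribute:
#'   a data.frame of excluded patients and the first applicable reason.
#' @export
identify_cases <- function(patients, events, ra_codes,
                           study_start, study_end) {
  stopifnot(inherits(ra_codes, "code_spec"), length(ra_codes$codes) > 0)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)

  ra_ev <- events[events$read_code %in% ra_codes$codes, , drop = FALSE]
  eff <- effective_date(ra_ev)
  first_ra <- tapply(eff, ra_ev$patient_id, min)
  index <- as.Date(rep(NA, nrow(patients)))
  hit <- match(patients$patient_id, names(first_ra))
  index[!is.na(hit)] <- as.Date(first_ra[hit[!is.na(hit)]],
                                origin = "1970-01-01")

  bounds <- observation_bounds(patients)
  age <- as.integer(format(index, "%Y")) - patients$year_of_birth
  win_start <- index - 365L
  win_end <- index + 14L

  reason <- rep(NA_character_, nrow(patients))
  assign_reason <- function(cond, label) {
    sel <- is.na(reason) & !is.na(cond) & cond
    reason[sel] <<- label
  }
  assign_reason(is.na(index), "no_ra_code")
  assign_reason(index < study_start, "index_before_study_start")
  assign_reason(index > study_end, "index_after_study_end")
  assign_reason(age < 30L, "under_30")
  assign_reason(!bounds$usable, "unusable_bounds")
  assign_reason(bounds$obs_start > win_start | bounds$obs_end < win_end,
                "window_not_covered")

  keep <- is.na(reason)
  cohort <- data.frame(
    patient_id = patients$patient_id[keep],
    gender = patients$gender[keep],
    year_of_birth = patients$year_of_birth[keep],
    index_date = index[keep],
    age_at_index = age[keep],
    window_start = win_start[keep],
    window_end = win_end[keep],
    obs_start = bounds$obs_start[keep],
    obs_end = bounds$obs_end[keep],
    stringsAsFactors = FALSE)
  exclusions <- data.frame(patient_id = patients$patient_id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  attr(cohort, "exclusions") <- exclusions
  cohort
}

#' Restrict events to the analysis and keyword-search windows
#'
#' Events outside a patient's observation bounds are always discarded.
#' `analysis` events fall in `[window_start, window_end]`; `search` events
#' (used only for keyword scanning) extend back to the earliest of the window
#' start, the first DMARD prescription and the first specific-marker code,
#' even when those predate the window.
#'
#' @param cohort Cohort data.frame from [identify_cases()].
#' @param events Events data.frame.
#' @param dmard_codes [code_spec()] for DMARD prescriptions.
#' @param marker_codes Character vector of specific-marker Read codes (the
#'   inflammatory-arthritis-diagnosis and synovitis lists).
#' @return List with `analysis` and `search` event data.frames (each with an
#'   `effective_date` column) and `cohort` augmented with `search_start`.
#' @export
window_events <- function(cohort, events, dmard_codes, marker_codes) {
  if (inherits(marker_codes, "code_spec")) marker_codes <- marker_codes$codes
  row <- match(events$patient_id, cohort$patient_id)
  in_cohort <- !is.na(row)
  ev <- events[in_cohort, , drop = FALSE]
  row <- row[in_cohort]
  ev$effective_date <- effective_date(ev)

  in_obs <- ev$effective_date >= cohort$obs_start[row] &
    ev$effective_date <= cohort$obs_end[row]
  ev <- ev[in_obs, , drop = FALSE]
  row <- row[in_obs]

  extender <- ev$read_code %in% c(dmard_codes$codes, marker_codes)
  first_ext <- tapply(ev$effective_date[extender], ev$patient_id[extender],
                      min)
  search_start <- cohort$window_start
  hit <- match(cohort$patient_id, names(first_ext))
  has <- !is.na(hit)
  search_start[has] <- pmin(search_start[has],
                            as.Date(first_ext[hit[has]],
                                    origin = "1970-01-01"))

  in_analysis <- ev$effective_date >= cohort$window_start[row] &
    ev$effective_date <= cohort$window_end[row]
  in_search <- ev$effective_date >= search_start[row] &
    ev$effective_date <= cohort$window_end[row]

  cohort$search_start <- search_start
  list(analysis = ev[in_analysis, , drop = FALSE],
       search = ev[in_search, , drop = FALSE],
       cohort = cohort)
}
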