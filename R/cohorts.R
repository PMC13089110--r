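# Amyloid-status classification and cohort assignment.
#
# Amyloid status comes from the nearest eligible measure within 2 years
# of baseline MRI.  PET (florbetapir or PiB) is preferred over CSF
# whenever any PET measure falls in the window, even if a CSF measure is
# temporally closer — the modality preference outranks recency.  PET
# cutoffs are inclusive (SUVR >= cutoff is positive); the CSF cutoff is
# strict (value < cutoff is positive).

#' Default amyloid positivity thresholds
#'
#' Florbetapir SUVR >= 1.1, PiB SUVR >= 1.47 (positive at or above),
#' CSF A-beta-42 < 980 pg/mL (positive strictly below).
#'
#' @return Named numeric vector of cutoffs.
#' @export
default_amyloid_thresholds <- function() {
  c(florbetapir = 1.1, PiB = 1.47, CSF_abeta42 = 980)
}

AMYLOID_PET <- c("florbetapir", "PiB")
AMYLOID_WINDOW_YEARS <- 2

#' Classify amyloid status from a participant's measures
#'
#' Among measures with |offset| <= 2 years, the PET measure with the
#' smallest |offset| is used when any PET measure is eligible, otherwise
#' the closest CSF measure.  Ties at equal |offset| prefer florbetapir
#' over PiB, then the earlier (more negative) offset.  With no eligible
#' measure the status is `"unknown"`.
#'
#' @param measures data.frame with columns `modality`
#'   (`florbetapir` / `PiB` / `CSF_abeta42`), `value`, `offset_years`,
#'   holding all measures for one participant.
#' @param thresholds named cutoffs, default [default_amyloid_thresholds()].
#' @return `"positive"`, `"negative"` or `"unknown"`.
#' @export
classify_amyloid <- function(measures, thresholds = default_amyloid_thresholds()) {
  if (nrow(measures) == 0) return("unknown")
  bad <- setdiff(unique(measures$modality), names(thresholds))
  if (length(bad) > 0) {
    cb_stop(paste("unrecognized amyloid modality:", paste(bad, collapse = ", ")),
            "cometbag_input_error")
  }
  eligible <- measures[abs(measures$offset_years) <= AMYLOID_WINDOW_YEARS, ,
                       drop = FALSE]
  if (nrow(eligible) == 0) return("unknown")
  is_pet <- eligible$modality %in% AMYLOID_PET
  pool <- if (any(is_pet)) eligible[is_pet, , drop = FALSE] else eligible
  # deterministic choice: smallest |offset|, then florbetapir before PiB,
  # then earlier date
  ord <- order(abs(pool$offset_years),
               match(pool$modality, c("florbetapir", "PiB", "CSF_abeta42")),
               pool$offset_years)
  chosen <- pool[ord[1], ]
  cutoff <- thresholds[[chosen$modality]]
  positive <- if (chosen$modality %in% AMYLOID_PET) {
    chosen$value >= cutoff
  } else {
    chosen$value < cutoff
  }
  if (positive) "positive" else "negative"
}

#' Classify amyloid status for a whole amyloid table
#'
#' @param amyloid data.frame with columns `participant_id`, `modality`,
#'   `value`, `offset_years`.
#' @param ids participant ids to classify (participants with no measures
#'   get `"unknown"`).
#' @inheritParams classify_amyloid
#' @return Named character vector of statuses.
#' @export
classify_amyloid_table <- function(amyloid, ids = unique(amyloid$participant_id),
                                   thresholds = default_amyloid_thresholds()) {
  out <- vapply(ids, function(p) {
    classify_amyloid(amyloid[amyloid$participant_id == p, , drop = FALSE],
                     thresholds)
  }, character(1))
  names(out) <- ids
  out
}

#' Assign study cohorts from diagnosis and amyloid status
#'
#' CU diagnosis with negative amyloid forms the cognitively-unimpaired
#' reference cohort; MCI or dementia with positive amyloid forms the
#' symptomatic cohort; every other combination (including unknown
#' amyloid) is excluded.
#'
#' @param participants participant table with columns `id`, `diagnosis`.
#' @param amyloid_status named character vector from
#'   [classify_amyloid_table()].
#' @return data.frame with `participant_id`, `amyloid_status`, `cohort`
#'   (`CU` / `symptomatic` / `excluded`).
#' @export
assign_cohort <- function(participants, amyloid_status) {
  status <- amyloid_status[participants$id]
  status[is.na(status)] <- "unknown"
  cohort <- ifelse(participants$diagnosis == "CU" & status == "negative", "CU",
            ifelse(participants$diagnosis %in% c("MCI", "dementia") &
                     status == "positive", "symptomatic", "excluded"))
  data.frame(participant_id = participants$id,
             amyloid_status = unname(status), cohort = cohort,
             stringsAsFactors = FALSE)
}

#' Chronological age group
#'
#' Younger: age <= 65 years; older: age >= 80 years; average otherwise.
#'
#' @param age_at_mri numeric ages in years (> 0).
#' @return Factor with levels younger, average, older.
#' @export
age_group <- function(age_at_mri) {
  if (any(age_at_mri <= 0) || anyNA(age_at_mri)) {
    cb_stop("age_at_mri must be positive", "cometbag_input_error")
  }
  factor(ifelse(age_at_mri <= 65, "younger",
                ifelse(age_at_mri >= 80, "older", "average")),
         levels = c("younger", "average", "older"))
}
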