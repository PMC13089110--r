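#' Validate pipeline input tables
#'
#' Checks schema, value ranges and id alignment across the participant,
#' ROI, amyloid and methylation tables.  Fatal violations (missing
#' required columns, beta values outside \[0, 1\], non-positive
#' structural values, participants in downstream tables absent from the
#' participant table) are collected and reported all at once; benign
#' irregularities (extra unused columns) are warnings.
#'
#' @param tables named list with any of `participants`, `roi`, `amyloid`,
#'   `methylation` (the last a numeric matrix).
#' @param roi_sets ROI definition used to check ROI completeness.
#' @return List with character vectors `errors` and `warnings`; valid
#'   input has `length(errors) == 0`.
#' @export
validate_inputs <- function(tables, roi_sets = default_roi_sets()) {
  errors <- character(0)
  warnings <- character(0)
  req <- list(
    participants = c("id", "age_at_mri", "sex", "education", "icv",
                     "diagnosis", "scanner_field"),
    amyloid = c("participant_id", "modality", "value", "offset_years"),
    roi = c("participant_id", "batch")
  )
  for (nm in intersect(names(req), names(tables))) {
    missing <- setdiff(req[[nm]], names(tables[[nm]]))
    if (length(missing) > 0) {
      errors <- c(errors, paste0(nm, ": missing column(s) ",
                                 paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(tables[[nm]]),
                     c(req[[nm]], "cdrsb", "apoe4_count",
                       if (nm == "roi") roi_all_columns(roi_sets)))
    if (length(extra) > 0) {
      warnings <- c(warnings, paste0(nm, ": unused column(s) ",
                                     paste(extra, collapse = ", ")))
    }
  }

  p <- tables$participants
  if (!is.null(p) && all(c("id", "age_at_mri", "icv", "diagnosis") %in% names(p))) {
    if (any(p$age_at_mri <= 0)) errors <- c(errors, "participants: non-positive age_at_mri")
    if (any(p$icv <= 0)) errors <- c(errors, "participants: non-positive icv")
    bad_dx <- setdiff(unique(p$diagnosis), c("CU", "MCI", "dementia"))
    if (length(bad_dx) > 0) {
      errors <- c(errors, paste("participants: unknown diagnosis",
                                paste(bad_dx, collapse = ", ")))
    }
    if (anyDuplicated(p$id)) errors <- c(errors, "participants: duplicated ids")
  }

  check_ids <- function(ids, nm) {
    if (is.null(p) || !"id" %in% names(p)) return(character(0))
    orphan <- setdiff(ids, p$id)
    if (length(orphan) > 0) {
      paste0(nm, ": participant(s) absent from participant table: ",
             paste(utils::head(orphan, 5), collapse = ", "))
    } else character(0)
  }

  r <- tables$roi
  if (!is.null(r)) {
    errors <- c(errors, check_ids(r$participant_id, "roi"))
    cols <- intersect(roi_all_columns(roi_sets), names(r))
    missing_roi <- setdiff(roi_all_columns(roi_sets), names(r))
    if (length(missing_roi) > 0) {
      errors <- c(errors, paste0("roi: missing ROI column(s) ",
                                 paste(utils::head(missing_roi, 5),
                                       collapse = ", ")))
    }
    for (cl in cols) {
      if (any(!is.finite(r[[cl]])) || any(r[[cl]] <= 0)) {
        errors <- c(errors, paste0("roi: non-finite or non-positive values in ", cl))
      }
    }
  }

  am <- tables$amyloid
  if (!is.null(am) && all(req$amyloid %in% names(am))) {
    errors <- c(errors, check_ids(am$participant_id, "amyloid"))
    if (any(am$value <= 0)) errors <- c(errors, "amyloid: non-positive values")
    bad_mod <- setdiff(unique(am$modality),
                       c("florbetapir", "PiB", "CSF_abeta42"))
    if (length(bad_mod) > 0) {
      errors <- c(errors, paste("amyloid: unknown modality",
                                paste(bad_mod, collapse = ", ")))
    }
  }

  m <- tables$methylation
  if (!is.null(m)) {
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
      errors <- c(errors, "methylation: beta values outside [0, 1]")
    }
    pid <- sub("_r[0-9]+$", "", rownames(m))
    if (anyDuplicated(rownames(m))) {
      errors <- c(errors, "methylation: duplicated (participant, replicate) keys")
    }
    errors <- c(errors, check_ids(unique(pid), "methylation"))
  }

  list(errors = errors, warnings = warnings)
}

stop_on_invalid <- function(tables, roi_sets = default_roi_sets()) {
  v <- validate_inputs(tables, roi_sets)
  for (w in v$warnings) warning(w, call. = FALSE)
  if (length(v$errors) > 0) {
    cb_stop(paste0("invalid inputs:\n  ", paste(v$errors, collapse = "\n  ")),
            "cometbag_input_error")
  }
  invisible(tables)
}
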