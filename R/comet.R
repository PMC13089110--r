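# CoMeT: cortical minus medial-temporal composite w-scores.
#
# Composites average the left and right hemisphere of each ROI, then
# average (unweighted) across the ROIs of the set.  w-scores adjust a
# composite for healthy-aging covariates using a regression fitted on
# the cognitively unimpaired (CU) reference only: age + sex for
# thickness composites, age + ICV for volume composites.  CoMeT is the
# cortical composite w-score minus the MTL composite w-score; lower
# CoMeT means relatively greater cortical involvement (a less typical
# presentation), higher CoMeT relatively greater MTL involvement.

#' Bilateral ROI composite
#'
#' Per ROI, the mean of the left and right hemisphere values; then the
#' unweighted mean across the ROIs of the set.
#'
#' @param roi ROI table (data.frame) with `lh_<roi>_<kind>` /
#'   `rh_<roi>_<kind>` columns.
#' @param roi_names character vector of ROI names.
#' @param kind `"thickness"` or `"volume"`.
#' @return Numeric vector (one value per row), named by
#'   `roi$participant_id` when present.
#' @export
composite <- function(roi, roi_names, kind = "thickness") {
  cols <- unlist(lapply(roi_names, function(r) {
    c(roi_column("lh", r, kind), roi_column("rh", r, kind))
  }))
  missing <- setdiff(cols, names(roi))
  if (length(missing) > 0) {
    cb_stop(paste("missing ROI column(s):", paste(missing, collapse = ", ")),
            "cometbag_input_error")
  }
  per_roi <- vapply(roi_names, function(r) {
    (roi[[roi_column("lh", r, kind)]] + roi[[roi_column("rh", r, kind)]]) / 2
  }, numeric(nrow(roi)))
  per_roi <- matrix(per_roi, nrow = nrow(roi))
  out <- rowMeans(per_roi)
  if (!is.null(roi$participant_id)) names(out) <- roi$participant_id
  out
}

#' Fit a w-score model on the CU reference
#'
#' Least-squares fit of the composite on age + sex (thickness) or
#' age + ICV (volume), with residual SD computed with denominator n - p
#' (p = number of fitted parameters, here 3).
#'
#' @param values numeric composite values for the reference cohort.
#' @param covariates data.frame with columns `age` and, depending on
#'   `kind`, `sex` (`"female"`/`"male"`) or `icv`.
#' @param kind `"thickness"` or `"volume"`.
#' @return An object of class `wscore_model`: coefficients, covariate
#'   kind, residual SD, reference size.
#' @export
fit_wscore_model <- function(values, covariates, kind = c("thickness", "volume")) {
  kind <- match.arg(kind)
  X <- wscore_design(covariates, kind)
  if (length(values) != nrow(X)) {
    cb_stop("values and covariates are not aligned", "cometbag_input_error")
  }
  if (length(values) <= ncol(X) + 1) {
    cb_stop("reference too small for the w-score fit", "cometbag_fit_error")
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), values)
  if (fit$rank < ncol(X) + 1) {
    cb_stop("singular w-score design", "cometbag_fit_error")
  }
  p <- ncol(X) + 1
  sigma <- sqrt(sum(fit$residuals^2) / (length(values) - p))
  if (sigma <= .Machine$double.eps^0.5) {
    cb_stop("zero residual variance in the w-score reference fit",
            "cometbag_fit_error")
  }
  structure(list(kind = kind, coefficients = fit$coefficients,
                 sigma = sigma, n = length(values), p = p),
            class = "wscore_model")
}

wscore_design <- function(covariates, kind) {
  need <- if (kind == "thickness") c("age", "sex") else c("age", "icv")
  missing <- setdiff(need, names(covariates))
  if (length(missing) > 0) {
    cb_stop(paste("missing covariate column(s):", paste(missing, collapse = ", ")),
            "cometbag_input_error")
  }
  if (kind == "thickness") {
    cbind(age = as.numeric(covariates$age),
          sexfemale = as.numeric(as.character(covariates$sex) == "female"))
  } else {
    cbind(age = as.numeric(covariates$age), icv = as.numeric(covariates$icv))
  }
}

#' @export
print.wscore_model <- function(x, ...) {
  cat(sprintf("<wscore_model> %s (age + %s), reference n = %d, residual SD %.4g\n",
              x$kind, if (x$kind == "thickness") "sex" else "ICV", x$n, x$sigma))
  invisible(x)
}

#' Covariate-adjusted w-score
#'
#' `w = (observed - predicted from the reference regression) / reference
#' residual SD`.  A CU reference scored with its own model has mean 0 by
#' construction and sample SD `sqrt((n - p) / (n - 1))`, slightly below
#' one because the residual SD uses denominator n - p.
#'
#' @param values observed composite values.
#' @param covariates covariate data.frame for these rows.
#' @param model a [fit_wscore_model()].
#' @return Numeric w-scores (unitless).
#' @export
wscore <- function(values, covariates, model) {
  stopifnot(inherits(model, "wscore_model"))
  X <- cbind(1, wscore_design(covariates, model$kind))
  predicted <- drop(X %*% model$coefficients)
  (values - predicted) / model$sigma
}

#' CoMeT: signed difference of composite w-scores
#'
#' @param cortical_w,mtl_w composite w-scores.
#' @return `cortical_w - mtl_w`.  Lower values indicate relatively
#'   greater cortical involvement; higher values relatively greater MTL
#'   involvement.
#' @export
comet_score <- function(cortical_w, mtl_w) cortical_w - mtl_w

#' MTL composite w-score
#'
#' The MTL mixes measure kinds (entorhinal/parahippocampal thickness,
#' hippocampal/amygdalar volume), each with its own covariate set, so
#' the two sub-composites are w-scored separately (thickness: age + sex;
#' volume: age + ICV) and averaged.
#'
#' @param roi ROI table.
#' @param covariates covariate data.frame for its rows.
#' @param thickness_model,volume_model [fit_wscore_model()]s fitted on
#'   the CU reference MTL sub-composites.
#' @param roi_sets ROI definition.
#' @return Numeric MTL w-scores.
#' @export
mtl_composite_w <- function(roi, covariates, thickness_model, volume_model,
                            roi_sets = default_roi_sets()) {
  wt <- wscore(composite(roi, roi_sets$mtl_thickness, "thickness"),
               covariates, thickness_model)
  wv <- wscore(composite(roi, roi_sets$mtl_volume, "volume"),
               covariates, volume_model)
  (wt + wv) / 2
}

#' Fit all CoMeT w-score models on the CU reference
#'
#' @param roi_cu ROI table restricted to the CU reference cohort.
#' @param covariates_cu covariates (`age`, `sex`, `icv`) for those rows.
#' @param roi_sets ROI definition.
#' @return List of `wscore_model`s: `cortical`, `mtl_thickness`,
#'   `mtl_volume`.
#' @export
fit_comet_models <- function(roi_cu, covariates_cu,
                             roi_sets = default_roi_sets()) {
  validate_roi_sets(roi_sets)
  list(
    cortical = fit_wscore_model(
      composite(roi_cu, roi_sets$cortical_thickness, "thickness"),
      covariates_cu, "thickness"),
    mtl_thickness = fit_wscore_model(
      composite(roi_cu, roi_sets$mtl_thickness, "thickness"),
      covariates_cu, "thickness"),
    mtl_volume = fit_wscore_model(
      composite(roi_cu, roi_sets$mtl_volume, "volume"),
      covariates_cu, "volume")
  )
}

#' Compute CoMeT for a ROI table
#'
#' @param roi ROI table (typically harmonized).
#' @param covariates covariate data.frame aligned with its rows (raw,
#'   unharmonized age/sex/ICV).
#' @param models model list from [fit_comet_models()].
#' @param roi_sets ROI definition.
#' @return data.frame: `participant_id`, `cortical_w`, `mtl_w`, `comet`.
#' @export
compute_comet <- function(roi, covariates, models,
                          roi_sets = default_roi_sets()) {
  cortical_w <- wscore(composite(roi, roi_sets$cortical_thickness, "thickness"),
                       covariates, models$cortical)
  mtl_w <- mtl_composite_w(roi, covariates, models$mtl_thickness,
                           models$mtl_volume, roi_sets)
  data.frame(participant_id = roi$participant_id,
             cortical_w = as.numeric(cortical_w),
             mtl_w = as.numeric(mtl_w),
             comet = comet_score(as.numeric(cortical_w), as.numeric(mtl_w)),
             stringsAsFactors = FALSE)
}
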