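#' Default region-of-interest sets for the CoMeT composites
#'
#' The cortical composite covers 18 bilateral DKT-atlas cortical thickness
#' regions spanning the classic Alzheimer's cortical signature; the MTL
#' composite covers entorhinal and parahippocampal thickness plus
#' hippocampal and amygdalar volume.  Names use FreeSurfer aparc/aseg
#' spelling; column names in a [RoiTable][roi_column] are
#' `lh_<roi>_thickness` / `rh_<roi>_volume` etc.
#'
#' A custom definition can be supplied anywhere a `roi_sets` argument is
#' accepted, as a list with elements `cortical_thickness`, `mtl_thickness`
#' and `mtl_volume` (disjoint character vectors).
#'
#' @return A named list of three character vectors.
#' @export
default_roi_sets <- function() {
  list(
    cortical_thickness = c(
      "inferiortemporal", "temporalpole", "superiorparietal", "precuneus",
      "supramarginal", "superiorfrontal", "middlefrontal", "fusiform",
      "inferiorparietal", "superiortemporal", "posteriorcingulate",
      "isthmuscingulate", "lateraloccipital", "middletemporal",
      "medialorbitofrontal", "cuneus", "lingual", "pericalcarine"
    ),
    mtl_thickness = c("entorhinal", "parahippocampal"),
    mtl_volume = c("hippocampus", "amygdala")
  )
}

#' Read a ROI-set definition from YAML
#'
#' @param path YAML file with keys `cortical_thickness`, `mtl_thickness`,
#'   `mtl_volume`.
#' @return A ROI-set list as in [default_roi_sets()].
#' @export
read_roi_sets <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("cortical_thickness", "mtl_thickness", "mtl_volume")
  if (!all(need %in% names(x))) {
    cb_stop(paste("ROI set file must define:", paste(need, collapse = ", ")),
            "cometbag_input_error")
  }
  lapply(x[need], as.character)
}

validate_roi_sets <- function(roi_sets) {
  all_rois <- unlist(roi_sets, use.names = FALSE)
  if (anyDuplicated(all_rois)) {
    cb_stop("ROI sets must be disjoint", "cometbag_input_error")
  }
  invisible(roi_sets)
}

#' Column name for one hemisphere of a ROI measure
#'
#' @param hemi `"lh"` or `"rh"`.
#' @param roi ROI name.
#' @param kind `"thickness"` (mm) or `"volume"` (mm^3).
#' @export
roi_column <- function(hemi, roi, kind) paste(hemi, roi, kind, sep = "_")

# Healthy-reference ROI means used by the synthetic generator.
# Thickness in mm (FreeSurfer-plausible), volumes in mm^3 per hemisphere.
roi_norms <- function() {
  c(
    inferiortemporal = 2.80, temporalpole = 3.60, superiorparietal = 2.15,
    precuneus = 2.30, supramarginal = 2.55, superiorfrontal = 2.70,
    middlefrontal = 2.50, fusiform = 2.70, inferiorparietal = 2.45,
    superiortemporal = 2.80, posteriorcingulate = 2.45,
    isthmuscingulate = 2.35, lateraloccipital = 2.20, middletemporal = 2.85,
    medialorbitofrontal = 2.40, cuneus = 1.90, lingual = 2.00,
    pericalcarine = 1.65,
    entorhinal = 3.35, parahippocampal = 2.70,
    hippocampus = 3700, amygdala = 1550
  )
}

roi_kind <- function(roi, roi_sets) {
  if (roi %in% roi_sets$mtl_volume) "volume" else "thickness"
}

# all (hemi x roi) column names for a roi_sets definition, in fixed order
roi_all_columns <- function(roi_sets) {
  rois <- unlist(roi_sets, use.names = FALSE)
  unlist(lapply(rois, function(r) {
    k <- roi_kind(r, roi_sets)
    c(roi_column("lh", r, k), roi_column("rh", r, k))
  }))
}
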