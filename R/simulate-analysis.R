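#' Run the full analysis on a synthetic cohort, in memory
#'
#' Convenience wrapper chaining every stage without file I/O: generate a
#' cohort and its methylation data, classify amyloid status and cohorts,
#' compute BAG, harmonize ROI measures (ComBat fitted on the CU
#' reference), fit w-score models on CU, compute CoMeT, and run the
#' primary analysis.  Used for simulation studies (e.g. coupling
#' recovery over many seeds); the file-based [run_pipeline()] is the
#' production path.
#'
#' @param config a [synthetic_config()].
#' @param k SD multiplier for biological age groups.
#' @param roi_sets ROI definition.
#' @return List: `cohort` (generator output), `betas`, `clocks`, `bag`,
#'   `labels`, `harmonized` (ROI table), `comet`, `analysis`.
#' @export
run_synthetic_analysis <- function(config = synthetic_config(), k = 0.5,
                                   roi_sets = default_roi_sets()) {
  cohort <- generate_cohort(config, roi_sets = roi_sets)
  clock_data <- generate_clock_data(cohort$participants, cohort$truth, config)
  participants <- cohort$participants

  status <- classify_amyloid_table(cohort$amyloid, ids = participants$id)
  labels <- assign_cohort(participants, status)

  ages <- stats::setNames(participants$age_at_mri, participants$id)
  bag <- compute_bag_table(clock_data$betas, clock_data$clocks, ages, k = k,
                           seed = derive_seed(config$seed, "replicate_selection"))

  feats <- roi_all_columns(roi_sets)
  combat_covs <- data.frame(age = participants$age_at_mri,
                            sex = participants$sex,
                            diagnosis = participants$diagnosis)
  cu <- labels$cohort == "CU"
  model <- fit_combat(cohort$roi[cu, feats, drop = FALSE],
                      combat_covs[cu, , drop = FALSE],
                      cohort$roi$batch[cu])
  harmonized <- cohort$roi
  harmonized[, feats] <- apply_combat(model, cohort$roi[, feats, drop = FALSE],
                                      combat_covs, cohort$roi$batch)

  w_covs <- data.frame(age = participants$age_at_mri, sex = participants$sex,
                       icv = participants$icv)
  models <- fit_comet_models(harmonized[cu, , drop = FALSE],
                             w_covs[cu, , drop = FALSE], roi_sets = roi_sets)
  comet <- compute_comet(harmonized, w_covs, models, roi_sets = roi_sets)

  analysis <- run_primary_analysis(comet, bag, labels, participants)

  list(cohort = cohort, betas = clock_data$betas, clocks = clock_data$clocks,
       truth = clock_data$truth, bag = bag, labels = labels,
       combat_model = model, harmonized = harmonized,
       wscore_models = models, comet = comet, analysis = analysis)
}
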