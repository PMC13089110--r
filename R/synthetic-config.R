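#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: an ADNI-like
#' cross-sectional cohort with two-scanner batch effects on regional
#' structural measures, age/sex/ICV covariate dependence,
#' diagnosis-dependent cortical and MTL atrophy, and a latent
#' per-participant biological age gap (BAG) coupled to the
#' cortical-minus-MTL atrophy contrast.
#'
#' Defaults reproduce the published cohort scale (329 cognitively
#' unimpaired, 378 MCI, 304 dementia; age centred at 74.84 y, SD 6.96;
#' 44.4\% female) and a latent BAG with SD 4 y measured by three clocks
#' with 2 y per-clock noise.
#'
#' @param n_cu,n_mci,n_dementia cohort sizes (counts, >= 0).
#' @param age_range ages are drawn from a normal distribution centred at
#'   74.84 y (SD 6.96 y) and truncated to this `(low, high)` range in years.
#' @param sex_ratio fraction female, in \[0, 1\].
#' @param batch_probs probability a participant is scanned at 1.5T (the
#'   remainder at 3T).
#' @param batch_shift additive scanner offset (mm on thickness ROIs; scaled
#'   proportionally for volume ROIs) applied to the 3T batch.
#' @param batch_scale multiplicative factor on measurement-noise SD in the
#'   3T batch.
#' @param age_slope_thickness cortical thinning slope, mm per year
#'   (negative); volume ROIs use the proportionally scaled slope.
#' @param sex_effect additive thickness difference for females, mm.
#' @param icv_mean_sd `(mean, sd)` of intracranial volume, mm^3.
#' @param atrophy_cortex,atrophy_mtl mean symptomatic atrophy of the
#'   cortical and MTL composites, in reference-SD units (negative).
#' @param contrast_sd SD of the per-subject cortical-minus-MTL atrophy
#'   contrast, reference-SD units.
#' @param bag_sd SD of the latent biological age gap, years (> 0).
#' @param coupling_rho target correlation between latent BAG and the
#'   atrophy contrast in symptomatic subjects, in \[-1, 1\].
#' @param clock_noise_sd per-clock age-prediction noise, years.
#' @param n_cpgs number of CpG columns in the methylation matrix (>= 150:
#'   the three synthetic clocks use disjoint 50-CpG supports).
#' @param measurement_noise_sd per-ROI measurement noise, mm (scaled for
#'   volumes).
#' @param replicate_fraction fraction of participants given a duplicate
#'   methylation row flagged as a technical replicate.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_cohort()], [generate_clock_data()]
#' @export
synthetic_config <- function(n_cu = 329, n_mci = 378, n_dementia = 304,
                             age_range = c(55, 95),
                             sex_ratio = 0.444,
                             batch_probs = 0.5,
                             batch_shift = 0.08,
                             batch_scale = 1.2,
                             age_slope_thickness = -0.01,
                             sex_effect = 0.05,
                             icv_mean_sd = c(1.45e6, 1.3e5),
                             atrophy_cortex = -2,
                             atrophy_mtl = -2.5,
                             contrast_sd = 4,
                             bag_sd = 4,
                             coupling_rho = 0.15,
                             clock_noise_sd = 2,
                             n_cpgs = 200,
                             measurement_noise_sd = 0.1,
                             replicate_fraction = 0.05,
                             seed = 1L) {
  check_number(n_cu, "n_cu", lower = 0, integer = TRUE)
  check_number(n_mci, "n_mci", lower = 0, integer = TRUE)
  check_number(n_dementia, "n_dementia", lower = 0, integer = TRUE)
  check_number(age_range, "age_range", lower = 0, len = 2)
  if (age_range[1] >= age_range[2]) {
    cb_stop("invalid configuration field `age_range`", "cometbag_config_error")
  }
  check_number(sex_ratio, "sex_ratio", lower = 0, upper = 1)
  check_number(batch_probs, "batch_probs", lower = 0, upper = 1)
  check_number(batch_shift, "batch_shift")
  check_number(batch_scale, "batch_scale", lower = 0)
  check_number(age_slope_thickness, "age_slope_thickness")
  check_number(sex_effect, "sex_effect")
  check_number(icv_mean_sd, "icv_mean_sd", lower = 0, len = 2)
  check_number(atrophy_cortex, "atrophy_cortex")
  check_number(atrophy_mtl, "atrophy_mtl")
  check_number(contrast_sd, "contrast_sd", lower = 0)
  check_number(bag_sd, "bag_sd")
  if (bag_sd <= 0) {
    cb_stop("invalid configuration field `bag_sd`", "cometbag_config_error")
  }
  check_number(coupling_rho, "coupling_rho", lower = -1, upper = 1)
  check_number(clock_noise_sd, "clock_noise_sd", lower = 0)
  check_number(n_cpgs, "n_cpgs", lower = 0, integer = TRUE)
  check_number(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  check_number(replicate_fraction, "replicate_fraction", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)

  structure(
    list(
      n_cu = as.integer(n_cu), n_mci = as.integer(n_mci),
      n_dementia = as.integer(n_dementia),
      age_range = as.numeric(age_range), sex_ratio = sex_ratio,
      batch_probs = batch_probs, batch_shift = batch_shift,
      batch_scale = batch_scale,
      age_slope_thickness = age_slope_thickness, sex_effect = sex_effect,
      icv_mean_sd = as.numeric(icv_mean_sd),
      atrophy_cortex = atrophy_cortex, atrophy_mtl = atrophy_mtl,
      contrast_sd = contrast_sd, bag_sd = bag_sd,
      coupling_rho = coupling_rho, clock_noise_sd = clock_noise_sd,
      n_cpgs = as.integer(n_cpgs),
      measurement_noise_sd = measurement_noise_sd,
      replicate_fraction = replicate_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  cohort: %d CU / %d MCI / %d dementia\n",
              x$n_cu, x$n_mci, x$n_dementia))
  cat(sprintf("  latent BAG sd %.2g y, coupling rho %.3g, clock noise %.2g y\n",
              x$bag_sd, x$coupling_rho, x$clock_noise_sd))
  cat(sprintf("  batch: shift %.3g, scale %.3g; seed %d\n",
              x$batch_shift, x$batch_scale, x$seed))
  invisible(x)
}
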