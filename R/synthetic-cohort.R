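# Synthetic ADNI-like cohort with planted, recorded ground truth.
#
# Construction notes (see the methods vignette for rationale):
#  * each table draws from its own sub-stream derived from config$seed,
#    so adding a table never perturbs earlier ones;
#  * symptomatic atrophy is planted at the composite level, expressed in
#    the generator's own reference-SD units (the measurement-noise SD of
#    the corresponding CU composite), so downstream w-scores recover the
#    planted values directly;
#  * the latent BAG and the cortical-minus-MTL atrophy contrast are drawn
#    jointly with correlation coupling_rho.

# truncated-normal draw via the probability-integral transform: one
# uniform per observation, deterministic under seed
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# measurement-noise SD of each composite in a CU reference scanned on the
# unshifted batch; used to express planted atrophy in reference-SD units
composite_sigmas <- function(config, roi_sets = default_roi_sets()) {
  sm <- config$measurement_noise_sd
  norms <- roi_norms()
  n_cort <- length(roi_sets$cortical_thickness)
  n_mtl_t <- length(roi_sets$mtl_thickness)
  vol_sd <- sm * norms[roi_sets$mtl_volume] / 2.5
  c(
    cortical = sm / sqrt(2 * n_cort),
    mtl_thickness = sm / sqrt(2 * n_mtl_t),
    mtl_volume = sqrt(sum(vol_sd^2 / 2)) / length(vol_sd)
  )
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a full cross-sectional cohort: participant demographics and
#' diagnosis, amyloid measures placed on the diagnosis-consistent side of
#' the positivity cutoffs, regional structural measures with covariate
#' effects, a two-scanner batch effect and diagnosis-dependent atrophy,
#' and a latent per-participant biological age gap coupled to the
#' cortical-minus-MTL atrophy contrast at `config$coupling_rho`.
#'
#' @param config a [synthetic_config()].
#' @param roi_sets ROI definition, default [default_roi_sets()].
#' @return A list with elements `participants`, `roi`, `amyloid`
#'   (data.frames) and `truth` (class `synthetic_truth`: per-participant
#'   latent BAG and planted atrophy, batch parameters, composite reference
#'   SDs; clock truth is added by [generate_clock_data()]).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_cu = 20, n_mci = 10,
#'                                            n_dementia = 10, seed = 42))
#' table(cohort$participants$diagnosis)
#' @export
generate_cohort <- function(config, roi_sets = default_roi_sets()) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_roi_sets(roi_sets)
  n <- config$n_cu + config$n_mci + config$n_dementia

  diagnosis <- rep(c("CU", "MCI", "dementia"),
                   c(config$n_cu, config$n_mci, config$n_dementia))
  ids <- sprintf("S%04d", seq_len(n))
  symptomatic <- diagnosis != "CU"

  ## -- participants ---------------------------------------------------
  set.seed(derive_seed(config$seed, "participants"))
  age <- rtruncnorm(n, 74.84, 6.96, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  education <- pmin(20, pmax(8, round(stats::rnorm(n, 15.8, 2.6))))
  icv <- stats::rnorm(n, config$icv_mean_sd[1], config$icv_mean_sd[2]) +
    ifelse(sex == "female", -0.75e5, 0.75e5)
  batch <- ifelse(stats::runif(n) < config$batch_probs, "1.5T", "3T")
  cdrsb <- numeric(n)
  cdrsb[diagnosis == "CU"] <- 0.5 * stats::rbinom(sum(diagnosis == "CU"), 1, 0.15)
  cdrsb[diagnosis == "MCI"] <- 0.5 * stats::rpois(sum(diagnosis == "MCI"), 3)
  cdrsb[diagnosis == "dementia"] <- 0.5 * stats::rpois(sum(diagnosis == "dementia"), 10)
  apoe4 <- integer(n)
  apoe4[!symptomatic] <- sample(0:2, sum(!symptomatic), TRUE, c(0.79, 0.19, 0.02))
  apoe4[symptomatic] <- sample(0:2, sum(symptomatic), TRUE, c(0.315, 0.50, 0.185))

  participants <- data.frame(
    id = ids, age_at_mri = age, sex = sex, education = education,
    icv = icv, diagnosis = diagnosis, scanner_field = batch,
    cdrsb = cdrsb, apoe4_count = apoe4, stringsAsFactors = FALSE
  )

  ## -- latent ground truth --------------------------------------------
  set.seed(derive_seed(config$seed, "latent"))
  g <- stats::rnorm(n, 0, config$bag_sd)
  rho <- config$coupling_rho
  z <- stats::rnorm(n)
  contrast_dev <- config$contrast_sd * (rho * g / config$bag_sd +
                                          sqrt(1 - rho^2) * z)
  atrophy_c <- ifelse(symptomatic, config$atrophy_cortex + contrast_dev / 2, 0)
  atrophy_m <- ifelse(symptomatic, config$atrophy_mtl - contrast_dev / 2, 0)

  sig <- composite_sigmas(config, roi_sets)

  truth <- structure(list(
    participants = data.frame(
      id = ids, diagnosis = diagnosis, latent_bag = g,
      atrophy_cortex = atrophy_c, atrophy_mtl = atrophy_m,
      atrophy_contrast = atrophy_c - atrophy_m, stringsAsFactors = FALSE
    ),
    batch = list(shifted_batch = "3T", shift_thickness = config$batch_shift,
                 noise_scale = config$batch_scale),
    composite_sigmas = as.list(sig),
    config = unclass(config),
    clocks = NULL
  ), class = "synthetic_truth")

  ## -- amyloid measures ------------------------------------------------
  set.seed(derive_seed(config$seed, "amyloid"))
  amyloid <- generate_amyloid(ids, symptomatic)

  ## -- ROI structural table ---------------------------------------------
  set.seed(derive_seed(config$seed, "roi"))
  roi <- generate_roi(participants, truth, config, roi_sets, sig)

  list(participants = participants, roi = roi, amyloid = amyloid,
       truth = truth)
}

# per-subject amyloid measures, values placed on the diagnosis-consistent
# side of the positivity cutoffs; ~30% of subjects get a second measure
# (possibly outside the 2-year window) to exercise the nearest-measure rule
generate_amyloid <- function(ids, symptomatic) {
  n <- length(ids)
  if (n == 0) {
    return(data.frame(participant_id = character(), modality = character(),
                      value = numeric(), offset_years = numeric(),
                      stringsAsFactors = FALSE))
  }
  draw_value <- function(modality, positive) {
    switch(modality,
      florbetapir = if (positive) rtruncnorm(1, 1.35, 0.15, 1.11, 2.2)
                    else rtruncnorm(1, 0.98, 0.07, 0.70, 1.09),
      PiB = if (positive) rtruncnorm(1, 1.80, 0.20, 1.49, 2.8)
            else rtruncnorm(1, 1.25, 0.10, 1.00, 1.45),
      CSF_abeta42 = if (positive) rtruncnorm(1, 650, 150, 200, 975)
                    else rtruncnorm(1, 1350, 250, 985, 2500)
    )
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    modality <- sample(c("florbetapir", "PiB", "CSF_abeta42"), 1,
                       prob = c(0.7, 0.1, 0.2))
    rec <- data.frame(
      participant_id = ids[i], modality = modality,
      value = draw_value(modality, symptomatic[i]),
      offset_years = stats::runif(1, -1.5, 1.5), stringsAsFactors = FALSE
    )
    if (stats::runif(1) < 0.3) {
      m2 <- sample(c("florbetapir", "CSF_abeta42"), 1)
      rec <- rbind(rec, data.frame(
        participant_id = ids[i], modality = m2,
        value = draw_value(m2, symptomatic[i]),
        offset_years = stats::runif(1, -4, 4), stringsAsFactors = FALSE
      ))
    }
    rows[[i]] <- rec
  }
  do.call(rbind, rows)
}

generate_roi <- function(participants, truth, config, roi_sets, sig) {
  n <- nrow(participants)
  cols <- roi_all_columns(roi_sets)
  roi <- data.frame(participant_id = participants$id,
                    batch = participants$scanner_field,
                    stringsAsFactors = FALSE)
  for (col in cols) roi[[col]] <- numeric(n)
  if (n == 0) return(roi)

  norms <- roi_norms()
  icv_mean <- config$icv_mean_sd[1]
  female <- participants$sex == "female"
  age_c <- participants$age_at_mri - 74.84
  shifted <- participants$scanner_field == truth$batch$shifted_batch
  noise_scale <- ifelse(shifted, config$batch_scale, 1)
  tp <- truth$participants

  for (r in unlist(roi_sets, use.names = FALSE)) {
    kind <- roi_kind(r, roi_sets)
    u <- if (kind == "volume") norms[[r]] / 2.5 else 1
    atrophy <- if (r %in% roi_sets$cortical_thickness) {
      tp$atrophy_cortex * sig[["cortical"]]
    } else if (r %in% roi_sets$mtl_thickness) {
      tp$atrophy_mtl * sig[["mtl_thickness"]]
    } else {
      tp$atrophy_mtl * sig[["mtl_volume"]]
    }
    mu <- norms[[r]] +
      config$age_slope_thickness * u * age_c +
      (if (kind == "thickness") config$sex_effect * female else 0) +
      (if (kind == "volume") (norms[[r]] / icv_mean) * (participants$icv - icv_mean) else 0) +
      config$batch_shift * u * shifted +
      atrophy
    for (h in c("lh", "rh")) {
      roi[[roi_column(h, r, kind)]] <-
        mu + stats::rnorm(n, 0, config$measurement_noise_sd * u) * noise_scale
    }
  }
  roi
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat(sprintf("  %d participants; latent BAG sd %.3g y\n",
              nrow(x$participants), stats::sd(x$participants$latent_bag)))
  cat(sprintf("  shifted batch: %s (shift %.3g, noise scale %.3g)\n",
              x$batch$shifted_batch, x$batch$shift_thickness,
              x$batch$noise_scale))
  cat(sprintf("  clocks recorded: %s\n",
              if (is.null(x$clocks)) "no" else "yes"))
  invisible(x)
}
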