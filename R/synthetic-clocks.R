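# Synthetic methylation betas and clock models.
#
# Betas are constructed as an affine map of the target predicted age
# through each clock's pseudoinverse: on clock k's CpG support,
#   beta = 0.5 + c_k (y - m0_k) / ||c_k||^2 + noise_perp,
# where y is the transformed target age and m0_k the predictor value of a
# flat 0.5 beta row.  noise_perp is CpG-level noise projected orthogonal
# to c_k, so apply_clock() recovers the target exactly:
#   apply_clock(betas, clock_k) = chronological age + latent BAG + N(0, clock_noise_sd).
# Centering at 0.5 gives maximal clipping headroom; coefficient scales
# are chosen so that realistic ages stay strictly inside [0, 1], and the
# generator errors out rather than clip a planted signal.

CPGS_PER_CLOCK <- 50L

#' Generate synthetic methylation betas and clock models
#'
#' Builds three synthetic clocks with known, recorded coefficients — one
#' log-linear-adult clock and two identity clocks, on disjoint 50-CpG
#' supports — and a beta matrix such that each clock's predicted age
#' equals chronological age + latent BAG + independent noise of SD
#' `config$clock_noise_sd`.  A fraction of participants receives a
#' duplicated row flagged as a technical replicate (`<id>_r2`), drawn
#' with fresh assay noise.
#'
#' @param participants participant table from [generate_cohort()].
#' @param truth the matching `synthetic_truth` (provides the latent BAG).
#' @param config the [synthetic_config()] used to generate the cohort.
#' @return A list: `betas` (matrix, rows = participants + replicates,
#'   columns = CpG ids), `clocks` (list of [clock_model()]), and `truth`
#'   updated with the clock ground truth.
#' @export
generate_clock_data <- function(participants, truth, config) {
  n <- nrow(participants)
  if (n == 0) {
    cb_stop("cannot generate clock data for an empty cohort",
            "cometbag_generation_error")
  }
  if (config$n_cpgs < 3 * CPGS_PER_CLOCK) {
    cb_stop(sprintf(
      "n_cpgs must be >= %d (three disjoint %d-CpG clock supports)",
      3 * CPGS_PER_CLOCK, CPGS_PER_CLOCK), "cometbag_config_error")
  }

  set.seed(derive_seed(config$seed, "methylation"))
  cpg_ids <- sprintf("cg%08d", seq_len(config$n_cpgs))

  specs <- list(
    list(name = "synthHorvath", transform = "log_linear_adult",
         coef_range = c(0.12, 0.18)),
    list(name = "synthHannum", transform = "identity",
         coef_range = c(3.2, 3.8)),
    list(name = "synthShireby", transform = "identity",
         coef_range = c(3.2, 3.8))
  )
  clocks <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    support <- cpg_ids[((k - 1) * CPGS_PER_CLOCK + 1):(k * CPGS_PER_CLOCK)]
    coefs <- stats::runif(CPGS_PER_CLOCK, s$coef_range[1], s$coef_range[2]) *
      sample(c(-1, 1), CPGS_PER_CLOCK, TRUE)
    names(coefs) <- support
    # intercept chosen so a flat beta row of 0.5 predicts the cohort
    # centre age (74.84 y)
    m_center <- if (s$transform == "identity") 74.84 else age_transform(74.84)
    clocks[[k]] <- clock_model(
      name = s$name, intercept = m_center - sum(coefs) * 0.5,
      coefficients = coefs, transform = s$transform
    )
  }

  # technical replicates: extra assay of the same participant
  n_rep <- round(config$replicate_fraction * n)
  rep_idx <- if (n_rep > 0) sort(sample.int(n, n_rep)) else integer(0)
  row_subject <- c(seq_len(n), rep_idx)
  rn <- c(participants$id,
          if (n_rep > 0) paste0(participants$id[rep_idx], "_r2"))

  lbag <- truth$participants$latent_bag[match(participants$id,
                                              truth$participants$id)]
  nrow_total <- length(row_subject)
  betas <- matrix(stats::rbeta(nrow_total * config$n_cpgs, 2, 2),
                  nrow = nrow_total, dimnames = list(rn, cpg_ids))

  for (k in seq_along(clocks)) {
    cl <- clocks[[k]]
    support <- names(cl$coefficients)
    cvec <- cl$coefficients
    c2 <- sum(cvec^2)
    m0 <- cl$intercept + sum(cvec) * 0.5
    target_age <- participants$age_at_mri[row_subject] + lbag[row_subject] +
      stats::rnorm(nrow_total, 0, config$clock_noise_sd)
    if (any(target_age <= 0)) {
      cb_stop("planted target age is non-positive; reduce bag_sd or clock noise",
              "cometbag_generation_error")
    }
    y <- if (cl$transform == "identity") target_age else
      age_transform(target_age, cl$adult_age)
    block <- 0.5 + outer(y - m0, cvec / c2)
    # CpG-level noise, projected orthogonal to the coefficient vector so
    # the planted prediction is untouched
    eta <- matrix(stats::rnorm(nrow_total * CPGS_PER_CLOCK, 0, 0.02),
                  nrow = nrow_total)
    eta <- eta - outer(drop(eta %*% cvec) / c2, cvec)
    block <- block + eta
    if (any(block < 0 | block > 1)) {
      cb_stop(paste0("clipping betas to [0,1] would destroy the planted ",
                     "signal of clock `", cl$name,
                     "`; narrow the age range or reduce bag_sd"),
              "cometbag_generation_error")
    }
    betas[, support] <- block
  }

  truth$clocks <- clocks
  list(betas = betas, clocks = clocks, truth = truth)
}
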