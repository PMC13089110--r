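test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_cu = -1), "n_cu",
               class = "cometbag_config_error")
  expect_error(synthetic_config(sex_ratio = 1.2), "sex_ratio",
               class = "cometbag_config_error")
  expect_error(synthetic_config(coupling_rho = -2), "coupling_rho",
               class = "cometbag_config_error")
  expect_error(synthetic_config(bag_sd = 0), "bag_sd",
               class = "cometbag_config_error")
})

test_that("an empty cohort yields empty tables and empty truth", {
  cohort <- generate_cohort(synthetic_config(n_cu = 0, n_mci = 0,
                                             n_dementia = 0))
  expect_equal(nrow(cohort$participants), 0)
  expect_equal(nrow(cohort$roi), 0)
  expect_equal(nrow(cohort$amyloid), 0)
  expect_equal(nrow(cohort$truth$participants), 0)
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ca <- generate_clock_data(a$participants, a$truth, cfg)
  cb <- generate_clock_data(b$participants, b$truth, cfg)
  expect_identical(ca$betas, cb$betas)
})

test_that("marginal distributions follow the configuration at n = 1000+", {
  cfg <- synthetic_config(n_cu = 1200, n_mci = 0, n_dementia = 0, seed = 3)
  cohort <- generate_cohort(cfg)
  p <- cohort$participants
  expect_lt(abs(mean(p$age_at_mri) - 74.84), 0.7)
  expect_lt(abs(mean(p$sex == "female") - 0.444), 0.05)
  expect_lt(abs(mean(p$icv) - 1.45e6) / 1.45e6, 0.03)
  expect_lt(abs(mean(p$scanner_field == "1.5T") - 0.5), 0.05)
  expect_lt(abs(sd(cohort$truth$participants$latent_bag) - 4), 0.4)
})

test_that("without a planted batch effect, per-batch ROI means differ only by noise", {
  pvals <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_cu = 120, n_mci = 0, n_dementia = 0,
                            batch_shift = 0, batch_scale = 1, seed = s)
    cohort <- generate_cohort(cfg)
    x <- composite(cohort$roi, default_roi_sets()$cortical_thickness)
    stats::t.test(x[cohort$roi$batch == "1.5T"],
                  x[cohort$roi$batch == "3T"])$p.value
  }, numeric(1))
  # p-values roughly uniform: no pile-up at zero, some mass above 0.5
  expect_lte(mean(pvals < 0.05), 0.25)
  expect_gte(mean(pvals > 0.3), 0.25)
})

test_that("the recorded latent BAG and atrophy contrast carry the planted coupling", {
  cfg <- synthetic_config(n_cu = 0, n_mci = 1000, n_dementia = 1000,
                          coupling_rho = 0.5, seed = 5)
  truth <- generate_cohort(cfg)$truth$participants
  expect_lt(abs(cor(truth$latent_bag, truth$atrophy_contrast) - 0.5), 0.05)
  # and the planted contrast means match the config in expectation
  expect_lt(abs(mean(truth$atrophy_contrast) - (-2 - (-2.5))), 0.3)
})

test_that("noiseless clocks reproduce age + latent BAG exactly", {
  cfg <- small_config(seed = 2, clock_noise_sd = 0, replicate_fraction = 0)
  cohort <- generate_cohort(cfg)
  cd <- generate_clock_data(cohort$participants, cohort$truth, cfg)
  target <- cohort$participants$age_at_mri +
    cohort$truth$participants$latent_bag
  for (cl in cd$clocks) {
    pred <- apply_clock(cd$betas, cl)
    expect_lt(max(abs(pred[cohort$participants$id] - target)), 1e-8)
  }
  expect_true(all(cd$betas >= 0 & cd$betas <= 1))
})

test_that("averaging three clock residuals beats any single clock", {
  cfg <- synthetic_config(n_cu = 400, n_mci = 0, n_dementia = 0, seed = 9,
                          replicate_fraction = 0)
  cohort <- generate_cohort(cfg)
  cd <- generate_clock_data(cohort$participants, cohort$truth, cfg)
  ages <- setNames(cohort$participants$age_at_mri, cohort$participants$id)
  bag <- compute_bag_table(cd$betas, cd$clocks, ages, seed = 1)
  g <- cohort$truth$participants$latent_bag[
    match(bag$participant_id, cohort$truth$participants$id)]
  err_avg <- var(bag$bag - g)
  err_single <- vapply(cd$clocks, function(cl) {
    var(bag[[paste0("bag_", cl$name)]] - g)
  }, numeric(1))
  expect_lt(err_avg, min(err_single))
})

test_that("planted BAG is recovered with r > 0.95 at clock noise 2 y, n = 500", {
  cfg <- synthetic_config(n_cu = 500, n_mci = 0, n_dementia = 0, seed = 13,
                          clock_noise_sd = 2)
  cohort <- generate_cohort(cfg)
  cd <- generate_clock_data(cohort$participants, cohort$truth, cfg)
  ages <- setNames(cohort$participants$age_at_mri, cohort$participants$id)
  bag <- compute_bag_table(cd$betas, cd$clocks, ages, seed = 1)
  g <- cohort$truth$participants$latent_bag[
    match(bag$participant_id, cohort$truth$participants$id)]
  expect_gt(cor(bag$bag, g), 0.95)
})

test_that("technical replicates are emitted and flagged", {
  cfg <- small_config(seed = 4, replicate_fraction = 0.2)
  cohort <- generate_cohort(cfg)
  cd <- generate_clock_data(cohort$participants, cohort$truth, cfg)
  reps <- grep("_r2$", rownames(cd$betas), value = TRUE)
  expect_equal(length(reps), round(0.2 * nrow(cohort$participants)))
  expect_false(anyDuplicated(rownames(cd$betas)) > 0)
})

test_that("a construction that cannot fit in [0,1] raises a generation error", {
  cfg <- small_config(seed = 1, bag_sd = 200)
  cohort <- generate_cohort(cfg)
  expect_error(generate_clock_data(cohort$participants, cohort$truth, cfg),
               class = "cometbag_generation_error")
})

test_that("amyloid values land on the diagnosis-consistent side of the cutoffs", {
  cohort <- generate_cohort(small_config(seed = 21))
  status <- classify_amyloid_table(cohort$amyloid, ids = cohort$participants$id)
  sym <- cohort$participants$diagnosis != "CU"
  expect_true(all(status[cohort$participants$id[sym]] == "positive"))
  expect_true(all(status[cohort$participants$id[!sym]] == "negative"))
})
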