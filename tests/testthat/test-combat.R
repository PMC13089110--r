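fixture_path <- system.file("extdata", "combat_fixture_synthetic.csv",
                            package = "cometbag")

test_that("fit + apply matches the independent parametric ComBat oracle", {
  fx <- read.csv(fixture_path, stringsAsFactors = FALSE)
  dat <- as.matrix(fx[, c("f1", "f2", "f3")])
  covs <- fx[, c("age", "sex")]
  model <- fit_combat(dat, covs, fx$batch)
  mine <- apply_combat(model, dat, covs, fx$batch)
  mod <- stats::model.matrix(~ age + sex, covs)
  oracle <- t(suppressMessages(
    sva::ComBat(dat = t(dat), batch = fx$batch, mod = mod, par.prior = TRUE)))
  expect_lt(max(abs(mine - oracle)), 1e-6)
})

test_that("with no planted batch effect the EB estimates are near the identity", {
  cfg <- synthetic_config(n_cu = 300, n_mci = 0, n_dementia = 0,
                          batch_shift = 0, batch_scale = 1, seed = 17)
  cohort <- generate_cohort(cfg)
  feats <- setdiff(names(cohort$roi), c("participant_id", "batch"))
  covs <- data.frame(age = cohort$participants$age_at_mri,
                     sex = cohort$participants$sex)
  model <- fit_combat(cohort$roi[, feats], covs, cohort$roi$batch)
  expect_lt(max(abs(model$gamma_star)), 0.25)
  expect_lt(max(abs(model$delta_star - 1)), 0.35)
})

test_that("a planted location shift is recovered in standardized units", {
  # single feature, sigma = 1, shift +0.3 in batch 2 (no-EB path)
  set.seed(23)
  n <- 30000
  batch <- rep(c("b1", "b2"), each = n)
  age <- runif(2 * n, 60, 90)
  x <- 0.02 * (age - 75) + rnorm(2 * n) + 0.3 * (batch == "b2")
  model <- fit_combat(matrix(x, ncol = 1, dimnames = list(NULL, "f")),
                      data.frame(age = age), batch)
  est <- (model$gamma_star["b2", "f"] - model$gamma_star["b1", "f"]) *
    sqrt(model$var_pooled[["f"]])
  expect_lt(abs(est - 0.3), 0.02)
})

test_that("the identity model returns its input unchanged", {
  fx <- read.csv(fixture_path, stringsAsFactors = FALSE)
  dat <- as.matrix(fx[, c("f1", "f2", "f3")])
  covs <- fx[, c("age", "sex")]
  model <- fit_combat(dat, covs, fx$batch)
  model$gamma_star[] <- 0
  model$delta_star[] <- 1
  out <- apply_combat(model, dat, covs, fx$batch)
  expect_lt(max(abs(out - dat)), 1e-10)
})

test_that("a single-feature model corrects its own training batches exactly", {
  set.seed(3)
  n <- 200
  batch <- rep(c("b1", "b2"), each = n)
  age <- runif(2 * n, 60, 90)
  x <- 2.5 - 0.01 * (age - 75) + rnorm(2 * n, 0, 0.1) + 0.2 * (batch == "b2")
  dat <- matrix(x, ncol = 1, dimnames = list(NULL, "f"))
  covs <- data.frame(age = age)
  model <- fit_combat(dat, covs, batch)
  out <- apply_combat(model, dat, covs, batch)
  # remove the model's own covariate contribution, then per-batch means
  # must coincide exactly
  adj <- out[, 1] - age * model$cov_coef["age", "f"]
  expect_lt(abs(mean(adj[batch == "b1"]) - mean(adj[batch == "b2"])), 1e-6)
})

test_that("EB shrinkage pulls per-feature batch estimates toward the prior", {
  cfg <- synthetic_config(n_cu = 300, n_mci = 0, n_dementia = 0, seed = 19)
  cohort <- generate_cohort(cfg)
  feats <- setdiff(names(cohort$roi), c("participant_id", "batch"))
  covs <- data.frame(age = cohort$participants$age_at_mri,
                     sex = cohort$participants$sex)
  model <- fit_combat(cohort$roi[, feats], covs, cohort$roi$batch)
  for (b in model$batches) {
    expect_lt(var(model$gamma_star[b, ]), var(model$gamma_hat[b, ]))
  }
})

test_that("row order does not matter: permuting rows permutes outputs", {
  fx <- read.csv(fixture_path, stringsAsFactors = FALSE)
  dat <- as.matrix(fx[, c("f1", "f2", "f3")])
  covs <- fx[, c("age", "sex")]
  model <- fit_combat(dat, covs, fx$batch)
  out <- apply_combat(model, dat, covs, fx$batch)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  out_perm <- apply_combat(model, dat[perm, ], covs[perm, ], fx$batch[perm])
  expect_equal(out_perm, out[perm, ], tolerance = 1e-12)
})

test_that("harmonization removes the batch effect in held-out symptomatic subjects", {
  # location shift only: with unequal batch noise scales the EB scale
  # correction also rescales the (out-of-reference) disease atrophy per
  # batch, which is a property of the method, not a defect
  res <- run_synthetic_analysis(synthetic_config(
    n_cu = 400, n_mci = 300, n_dementia = 300, batch_scale = 1, seed = 29))
  sym <- res$labels$cohort == "symptomatic"
  x <- composite(res$harmonized[sym, ], default_roi_sets()$cortical_thickness)
  p <- res$cohort$participants[sym, ]
  fit <- summary(stats::lm(x ~ p$age_at_mri + p$sex + p$diagnosis +
                             (res$harmonized$batch[sym] == "3T")))
  p_batch <- fit$coefficients[nrow(fit$coefficients), 4]
  expect_gt(p_batch, 0.01)
  # before harmonization the same shift is grossly significant
  x0 <- composite(res$cohort$roi[sym, ], default_roi_sets()$cortical_thickness)
  fit0 <- summary(stats::lm(x0 ~ p$age_at_mri + p$sex + p$diagnosis +
                              (res$cohort$roi$batch[sym] == "3T")))
  expect_lt(fit0$coefficients[nrow(fit0$coefficients), 4], 1e-10)
})

test_that("the planted age slope survives harmonization", {
  res <- run_synthetic_analysis(synthetic_config(
    n_cu = 500, n_mci = 0, n_dementia = 0, seed = 37))
  x <- composite(res$harmonized, default_roi_sets()$cortical_thickness)
  slope <- coef(stats::lm(x ~ res$cohort$participants$age_at_mri))[2]
  expect_lt(abs(slope - (-0.01)), 0.002)
})

test_that("fit and apply validate their inputs", {
  fx <- read.csv(fixture_path, stringsAsFactors = FALSE)
  dat <- as.matrix(fx[, c("f1", "f2", "f3")])
  covs <- fx[, c("age", "sex")]
  expect_error(fit_combat(dat, covs, rep("one", 8)),
               class = "cometbag_fit_error")
  expect_error(fit_combat(dat, covs, c("a", rep("b", 7))),
               class = "cometbag_fit_error")
  # covariate perfectly confounded with batch
  expect_error(fit_combat(dat, data.frame(bad = as.numeric(fx$batch == "3T")),
                          fx$batch),
               class = "cometbag_fit_error")
  model <- fit_combat(dat, covs, fx$batch)
  expect_error(apply_combat(model, dat, covs, rep("7T", 8)),
               class = "cometbag_application_error")
})

test_that("a fitted model survives JSON serialization", {
  fx <- read.csv(fixture_path, stringsAsFactors = FALSE)
  dat <- as.matrix(fx[, c("f1", "f2", "f3")])
  covs <- fx[, c("age", "sex")]
  model <- fit_combat(dat, covs, fx$batch)
  path <- tempfile(fileext = ".json")
  write_combat_model(model, path)
  back <- read_combat_model(path)
  expect_equal(apply_combat(back, dat, covs, fx$batch),
               apply_combat(model, dat, covs, fx$batch), tolerance = 1e-12)
})
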