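test_that("the log-linear anti-transform inverts the transform with fixed point 20", {
  expect_equal(age_anti_transform(0), 20)
  x <- c(0.5, 1, 5, 19.9, 20, 20.1, 45, 74.84, 120)
  expect_lt(max(abs(age_anti_transform(age_transform(x)) - x)), 1e-9)
})

test_that("a constant clock predicts its intercept for everyone", {
  m <- matrix(runif(10), nrow = 2,
              dimnames = list(c("a", "b"), paste0("cg", 1:5)))
  cl <- clock_model("const", intercept = 50,
                    coefficients = setNames(rep(0, 5), paste0("cg", 1:5)))
  expect_equal(unname(apply_clock(m, cl)), c(50, 50))
})

test_that("missing clock CpGs raise an error listing the missing ids", {
  m <- matrix(0.5, 1, 2, dimnames = list("a", c("cg1", "cg2")))
  cl <- clock_model("c", 0, setNames(c(1, 1), c("cg1", "cg9")))
  expect_error(apply_clock(m, cl), "cg9", class = "cometbag_input_error")
})

test_that("BAG residuals match the closed-form simple-regression oracle", {
  chron <- c(60, 70, 80)
  pred <- c(58, 75, 77)
  expect_equal(unname(compute_bag(pred, chron)),
               ols_residuals_oracle(pred, chron), tolerance = 1e-12)
  # a perfect clock and a constant-shifted clock both give zero residuals
  expect_equal(max(abs(compute_bag(chron, chron))), 0, tolerance = 1e-12)
  expect_equal(max(abs(compute_bag(chron + 7, chron))), 0, tolerance = 1e-12)
})

test_that("BAG regression requires a non-degenerate design", {
  expect_error(compute_bag(c(1, 2, 3), c(70, 70, 70)),
               class = "cometbag_estimation_error")
  expect_error(compute_bag(c(1, 2), c(60, 70)),
               class = "cometbag_estimation_error")
})

test_that("BAG is uncorrelated with chronological age on the fitting cohort", {
  set.seed(42)
  chron <- runif(200, 55, 95)
  pred <- 5 + 0.9 * chron + rnorm(200, 0, 4)
  res <- compute_bag(pred, chron)
  expect_lt(abs(cor(res, chron)), 1e-10)
  expect_lt(abs(mean(res)), 1e-10)
})

test_that("average_bag is the element-wise mean and checks alignment", {
  v <- setNames(rnorm(5), paste0("p", 1:5))
  expect_equal(average_bag(list(a = v, b = v, c = v)), v)
  r <- list(a = setNames(c(2, 1), c("x", "y")),
            b = setNames(c(-2, 1), c("x", "y")),
            c = setNames(c(0, 1), c("x", "y")))
  expect_equal(average_bag(r), setNames(c(0, 1), c("x", "y")))
  # brute-force recomputation on random input, including reordered names
  set.seed(1)
  vs <- lapply(1:3, function(i) setNames(rnorm(6), paste0("p", 1:6)))
  shuffled <- c(vs[1], lapply(vs[-1], function(v) v[sample(names(v))]))
  manual <- (vs[[1]] + vs[[2]] + vs[[3]]) / 3
  expect_equal(average_bag(shuffled), manual, tolerance = 1e-12)
  bad <- list(a = setNames(1:3, c("p", "q", "r")),
              b = setNames(1:3, c("p", "q", "z")))
  expect_error(average_bag(bad), class = "cometbag_alignment_error")
})

test_that("stratification uses inclusive +/- k boundaries on the cohort z-score", {
  # integer vector with exact mean 0 and exact sample SD 2 (sum of
  # squares 40 over n - 1 = 10), so z = x / 2 has exact 0.5 boundaries
  x <- c(-4, -1, -1, -1, -1, 0, 1, 1, 1, 1, 4)
  expect_equal(sd(x), 2)
  expect_equal(as.character(stratify_bag(x, k = 0.5)),
               c("decelerated", rep("decelerated", 4), "neutral",
                 rep("accelerated", 4), "accelerated"))
  expect_error(stratify_bag(rep(1, 5)), class = "cometbag_stratification_error")
})

test_that("group assignment is invariant to affine rescaling of the BAG", {
  set.seed(8)
  bag <- rnorm(300)
  expect_equal(stratify_bag(bag), stratify_bag(3.2 * bag + 17))
})

test_that("the accelerated fraction matches the Gaussian tail at large n", {
  set.seed(5)
  groups <- stratify_bag(rnorm(1e5))
  expect_lt(abs(mean(groups == "accelerated") - pnorm(-0.5)), 0.01)
  expect_lt(abs(mean(groups == "decelerated") - pnorm(-0.5)), 0.01)
})

test_that("replicate selection is deterministic, uniform, and keeps singletons", {
  m <- matrix(runif(8 * 3), nrow = 8, dimnames = list(
    c("p1", "p1_r2", "p2", "p3", "p3_r2", "p3_r3", "p4", "p5"),
    paste0("cg", 1:3)))
  s1 <- select_replicate(m, seed = 11)
  s2 <- select_replicate(m, seed = 11)
  expect_identical(s1, s2)
  expect_equal(rownames(s1), c("p1", "p2", "p3", "p4", "p5"))
  expect_equal(s1["p4", ], m["p4", ])  # singleton rows pass through
  # uniformity: over many seeds each of p3's three replicates is chosen
  picks <- vapply(1:300, function(s) {
    sel <- select_replicate(m, seed = s)
    which(apply(m[4:6, ], 1, function(r) all(r == sel["p3", ])))
  }, numeric(1))
  counts <- table(factor(picks, levels = 1:3))
  # multinomial(300, 1/3): each count within ~4 sd of 100
  expect_true(all(counts > 67 & counts < 133))
})

test_that("clock files round-trip through the CSV format", {
  cl <- clock_model("demo", intercept = 1.25,
                    coefficients = setNames(c(0.5, -1.25, 2), paste0("cg", 1:3)),
                    transform = "log_linear_adult", adult_age = 20)
  path <- tempfile(fileext = ".csv")
  write_clock_model(cl, path)
  back <- read_clock_model(path)
  expect_equal(back$name, "demo")
  expect_equal(back$intercept, 1.25)
  expect_equal(back$coefficients, cl$coefficients)
  expect_equal(back$transform, "log_linear_adult")
  expect_error(read_clock_model(tempfile()), class = "cometbag_input_error")
})
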