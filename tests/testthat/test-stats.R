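test_that("pearson matches the closed-form product-moment computation", {
  x <- c(1, 2, 4, 7)
  y <- c(2.3, 1.9, 4.4, 5.1)
  res <- pearson(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  # perfect linear relation
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), class = "cometbag_input_error")
  expect_error(pearson(1:2, 1:2), class = "cometbag_input_error")
})

test_that("rank-biserial equals brute-force pairwise dominance, ties shared", {
  expect_equal(rank_biserial(c(1, 2), c(3, 4)), -1)
  expect_equal(rank_biserial(c(3, 4), c(1, 2)), 1)
  expect_equal(rank_biserial(c(1, 3), c(2, 4)), -0.5)
  expect_equal(rank_biserial(c(5, 1, 3), c(5, 1, 3)), 0)
  set.seed(12)
  for (i in 1:40) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sample(1:6, na, TRUE)  # small support forces ties
    b <- sample(1:6, nb, TRUE)
    expect_equal(rank_biserial(a, b), brute_rank_biserial(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the minimal rank-sum configuration has exact one-sided p = 1/6", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$W, 3)  # minimum attainable for n_a = 2
  expect_equal(res$method, "exact")
  expect_equal(res$p_less, 1 / 6)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$rank_biserial, -1)
})

test_that("identical groups give a symmetric, null comparison", {
  res <- wilcoxon_rank_sum(c(2, 2, 5, 9), c(2, 2, 5, 9))
  expect_equal(res$rank_biserial, 0)
  expect_gt(res$p_value, 0.9)
})

test_that("exact enumeration agrees with stats::wilcox.test", {
  set.seed(31)
  for (i in 1:15) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb)
    res <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(res$U, unname(ref$statistic))
    if (res$method == "exact") {
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("the tie-corrected normal approximation agrees with stats::wilcox.test", {
  set.seed(32)
  for (i in 1:10) {
    a <- sample(1:10, 25, TRUE)
    b <- sample(1:10, 30, TRUE) + sample(0:1, 30, TRUE)
    res <- wilcoxon_rank_sum(a, b)
    expect_equal(res$method, "approx")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("W stays inside its attainable range and flips with group order", {
  set.seed(33)
  a <- rnorm(9); b <- rnorm(14)
  res <- wilcoxon_rank_sum(a, b)
  lo <- res$n_a * (res$n_a + 1) / 2
  expect_gte(res$W, lo)
  expect_lte(res$W, lo + res$n_a * res$n_b)
  flipped <- wilcoxon_rank_sum(b, a)
  expect_equal(flipped$rank_biserial, -res$rank_biserial, tolerance = 1e-12)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-12)
})

test_that("chi-squared matches the hand formula and detects independence", {
  res <- chi_squared(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # table proportional to the outer product of its margins
  outer_tab <- outer(c(2, 3), c(1, 4)) * 10
  expect_equal(chi_squared(outer_tab)$statistic, 0, tolerance = 1e-12)
  uni <- matrix(7, 3, 3)
  res3 <- chi_squared(uni)
  expect_equal(res3$statistic, 0, tolerance = 1e-12)
  expect_equal(res3$df, 4)
  expect_error(chi_squared(matrix(c(0, 0, 3, 4), 2)),
               class = "cometbag_input_error")
  expect_error(chi_squared(matrix(1:3, 3, 1)), class = "cometbag_input_error")
})

test_that("descriptives handle degenerate cohorts without crashing", {
  p <- data.frame(id = c("a", "b"), age_at_mri = c(70, 75),
                  sex = c("female", "male"), education = c(16, 12),
                  icv = c(1.4e6, 1.5e6), diagnosis = c("CU", "MCI"),
                  scanner_field = c("1.5T", "3T"), cdrsb = c(0, 3),
                  apoe4_count = c(0, 1), stringsAsFactors = FALSE)
  lab <- data.frame(participant_id = c("a", "b"),
                    amyloid_status = c("negative", "positive"),
                    cohort = c("CU", "symptomatic"), stringsAsFactors = FALSE)
  d <- describe_cohorts(p, lab)
  expect_equal(d$n, c(1, 1, 0))
  expect_match(d$age[1], "NA")        # single subject: SD undefined
  expect_equal(d$pct_female[1], 100)
  expect_true(is.na(d$pct_female[3])) # empty cohort row, no crash
})

test_that("descriptives recover the generator's configuration at scale", {
  res <- run_synthetic_analysis(dnam_scale_config(seed = 53))
  d <- describe_cohorts(res$cohort$participants, res$labels, res$bag)
  sym <- d[d$cohort == "symptomatic", ]
  expect_equal(sym$n, 285)
  age_mean <- as.numeric(sub(" .*", "", sym$age))
  expect_lt(abs(age_mean - 74.84), 1.5)
  expect_lt(abs(sym$pct_female - 44.4), 10)
  # biological age groups partition to 100%
  expect_equal(sym$pct_accelerated + sym$pct_neutral + sym$pct_decelerated,
               100, tolerance = 1e-9)
})

test_that("the primary analysis reports all comparisons for all cohorts", {
  res <- run_synthetic_analysis(small_config(seed = 59))
  tab <- res$analysis$table
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$analysis),
                  c("pearson_comet_bag", "wilcoxon_comet_decel_vs_accel",
                    "wilcoxon_comet_younger_vs_older"))
  expect_setequal(unique(tab$cohort), c("symptomatic", "dementia", "CU"))
})

test_that("undersized groups are reported as not computable, not a crash", {
  cfg <- synthetic_config(n_cu = 40, n_mci = 3, n_dementia = 3, seed = 61)
  res <- run_synthetic_analysis(cfg)
  tab <- res$analysis$table
  notes <- tab$note[tab$analysis == "wilcoxon_comet_younger_vs_older" &
                      tab$cohort == "dementia"]
  expect_true(all(nzchar(tab$note) | !is.na(tab$p_value)))
  expect_true(any(nzchar(tab$note)))
})

test_that("a strong planted coupling yields the expected comparison signs", {
  res <- run_synthetic_analysis(synthetic_config(
    n_cu = 120, n_mci = 80, n_dementia = 80, coupling_rho = 0.8, seed = 67))
  tab <- res$analysis$table
  row <- tab[tab$analysis == "wilcoxon_comet_decel_vs_accel" &
               tab$cohort == "symptomatic", ]
  expect_lt(row$estimate, 0)   # decelerated group has lower CoMeT
  expect_lt(row$p_value, 0.01)
  cor_row <- tab[tab$analysis == "pearson_comet_bag" &
                   tab$cohort == "symptomatic", ]
  expect_gt(cor_row$estimate, 0.4)
})
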