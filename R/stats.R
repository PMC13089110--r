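# Statistical battery: Pearson correlation, Wilcoxon rank-sum with
# rank-biserial effect size, chi-squared association, and Table-1 style
# cohort descriptives.  Two-sided p-values throughout; no multiple-
# testing correction.

#' Pearson correlation with a t-reference p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List: `n`, `r`, `p_value` (two-sided, t with n - 2 df).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    cb_stop("pearson needs equal-length vectors with n >= 3",
            "cometbag_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cb_stop("correlation undefined: zero variance", "cometbag_input_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(n = length(x), r = unname(ct$estimate), p_value = ct$p.value)
}

#' Rank-biserial correlation
#'
#' Mean pairwise dominance: `(#pairs a > b - #pairs a < b) / (n_a n_b)`,
#' ties contributing 0; equivalently `2 U_a / (n_a n_b) - 1` with ties
#' shared.  Negative values mean group `a` tends to be lower.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return Value in \[-1, 1\].
#' @export
rank_biserial <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    cb_stop("rank_biserial needs non-empty groups", "cometbag_input_error")
  }
  r <- rank(c(a, b))
  na <- length(a)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # midranks share ties
  2 * u_a / (na * length(b)) - 1
}

#' Wilcoxon rank-sum test with rank-biserial effect size
#'
#' Midranks for ties; the reported statistic `W` is the rank sum of
#' group `a`.  The exact p-value is computed by full enumeration of rank
#' assignments when `n_a + n_b <= 12` and there are no ties; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b numeric vectors (non-empty).
#' @param method `"auto"` (default switchover rule), `"exact"` or
#'   `"approx"`.
#' @return List of class `rank_sum_test`: group sizes, `W`, `U`,
#'   two-sided `p_value`, one-sided `p_less` / `p_greater`,
#'   `rank_biserial`, and the `method` used.
#' @export
wilcoxon_rank_sum <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) {
    cb_stop("wilcoxon_rank_sum needs non-empty groups", "cometbag_input_error")
  }
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  ties <- anyDuplicated(c(a, b)) > 0
  if (method == "auto") {
    method <- if (na + nb <= 12 && !ties) "exact" else "approx"
  }
  if (method == "exact") {
    p <- rank_sum_exact(r, na, W)
  } else {
    p <- rank_sum_approx(r, na, nb, W)
  }
  structure(list(
    n_a = na, n_b = nb, W = W, U = W - na * (na + 1) / 2,
    p_value = p$two, p_less = p$less, p_greater = p$greater,
    rank_biserial = rank_biserial(a, b), method = method
  ), class = "rank_sum_test")
}

# exact null distribution of the rank sum by full enumeration of which
# ranks fall in group a (works with midranks too)
rank_sum_exact <- function(r, na, W) {
  sets <- utils::combn(length(r), na)
  sums <- colSums(matrix(r[sets], nrow = na))
  tol <- 1e-9
  less <- mean(sums <= W + tol)
  greater <- mean(sums >= W - tol)
  list(two = min(1, 2 * min(less, greater)), less = less, greater = greater)
}

# normal approximation with tie-corrected variance and continuity correction
rank_sum_approx <- function(r, na, nb, W) {
  N <- na + nb
  E <- na * (N + 1) / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  V <- na * nb / 12 * ((N + 1) - tie_term)
  if (V <= 0) return(list(two = 1, less = 1, greater = 1))
  z <- W - E
  zc <- (z - sign(z) * 0.5) / sqrt(V)
  list(two = 2 * stats::pnorm(-abs(zc)),
       less = stats::pnorm((z + 0.5) / sqrt(V)),
       greater = stats::pnorm(-(z - 0.5) / sqrt(V)))
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (%s): W = %g, p = %.4g, rank-biserial = %.3f (n = %d, %d)\n",
    x$method, x$W, x$p_value, x$rank_biserial, x$n_a, x$n_b))
  invisible(x)
}

#' Pearson chi-squared test of association
#'
#' Without continuity correction; `df = (rows - 1)(cols - 1)`.
#'
#' @param tab two-way contingency table (matrix of counts).
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2)) {
    cb_stop("chi_squared needs a two-way table (>= 2 rows and columns)",
            "cometbag_input_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    cb_stop("chi_squared: zero marginal total", "cometbag_input_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

med_iqr <- function(x) {
  if (length(x) == 0 || all(is.na(x))) return("NA")
  sprintf("%.3g (%.3g)", stats::median(x, na.rm = TRUE),
          stats::IQR(x, na.rm = TRUE))
}

mean_sd <- function(x) {
  if (length(x) == 0 || all(is.na(x))) return("NA")
  s <- if (length(x) < 2) NA_real_ else stats::sd(x, na.rm = TRUE)
  sprintf("%.4g (%s)", mean(x, na.rm = TRUE),
          if (is.na(s)) "NA" else sprintf("%.3g", s))
}

#' Cohort descriptives table
#'
#' Per cohort: n, age and BAG as mean (SD), percent female and percent
#' APOE4 carrier, CDRSB and education as median (IQR), and biological
#' age group percentages.  With fewer than two subjects the SD is
#' reported as NA; an empty cohort yields a row of n = 0 without error.
#'
#' @param participants participant table.
#' @param cohort_labels [assign_cohort()] output.
#' @param bag_results optional [compute_bag_table()] output.
#' @return data.frame, one row per cohort.
#' @export
describe_cohorts <- function(participants, cohort_labels, bag_results = NULL) {
  merged <- merge(participants, cohort_labels, by.x = "id",
                  by.y = "participant_id", all.x = TRUE)
  if (!is.null(bag_results)) {
    merged <- merge(merged,
                    bag_results[, c("participant_id", "bag", "bio_age_group")],
                    by.x = "id", by.y = "participant_id", all.x = TRUE)
  }
  rows <- lapply(c("CU", "symptomatic", "excluded"), function(coh) {
    d <- merged[!is.na(merged$cohort) & merged$cohort == coh, , drop = FALSE]
    n <- nrow(d)
    pct <- function(x) if (n == 0) NA_real_ else 100 * mean(x, na.rm = TRUE)
    grp_pct <- function(g) {
      if (is.null(d$bio_age_group) || all(is.na(d$bio_age_group))) return(NA_real_)
      100 * mean(d$bio_age_group == g, na.rm = TRUE)
    }
    data.frame(
      cohort = coh, n = n,
      age = if (n) mean_sd(d$age_at_mri) else "NA",
      pct_female = pct(d$sex == "female"),
      pct_apoe4_carrier = pct(d$apoe4_count >= 1),
      cdrsb = if (n) med_iqr(d$cdrsb) else "NA",
      education = if (n) med_iqr(d$education) else "NA",
      bag = if (n && !is.null(d$bag)) mean_sd(d$bag[!is.na(d$bag)]) else "NA",
      pct_accelerated = grp_pct("accelerated"),
      pct_neutral = grp_pct("neutral"),
      pct_decelerated = grp_pct("decelerated"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
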