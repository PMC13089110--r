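# Primary analysis report: associations between CoMeT and biological /
# chronological age within the symptomatic cohort (and its dementia-only
# subset), plus null checks in the CU reference.
#
# Fixed group-order conventions: (decelerated, accelerated) and
# (younger, older), so a negative rank-biserial correlation means the
# first-named group has lower CoMeT.

analysis_row <- function(analysis, cohort, n_a = NA, n_b = NA,
                         statistic = NA, estimate = NA, p_value = NA,
                         note = "") {
  data.frame(analysis = analysis, cohort = cohort, n_a = n_a, n_b = n_b,
             statistic = statistic, estimate = estimate, p_value = p_value,
             note = note, stringsAsFactors = FALSE)
}

comet_bag_cor_row <- function(d, cohort) {
  if (nrow(d) < 3) {
    return(analysis_row("pearson_comet_bag", cohort, n_a = nrow(d),
                        note = "not computable: fewer than 3 subjects"))
  }
  ct <- pearson(d$comet, d$bag)
  analysis_row("pearson_comet_bag", cohort, n_a = ct$n,
               statistic = ct$r, estimate = ct$r, p_value = ct$p_value)
}

comet_group_row <- function(d, groups, first, second, analysis, cohort) {
  x <- d$comet[groups == first]
  y <- d$comet[groups == second]
  if (length(x) < 2 || length(y) < 2) {
    return(analysis_row(analysis, cohort, n_a = length(x), n_b = length(y),
                        note = "not computable: group size < 2"))
  }
  wt <- wilcoxon_rank_sum(x, y)
  analysis_row(analysis, cohort, n_a = wt$n_a, n_b = wt$n_b,
               statistic = wt$W, estimate = wt$rank_biserial,
               p_value = wt$p_value)
}

#' Run the primary CoMeT-vs-biological-age analysis
#'
#' For the symptomatic cohort and its dementia-only subset: (1) Pearson
#' correlation of CoMeT with BAG; (2) Wilcoxon rank-sum comparison of
#' CoMeT between decelerated and accelerated biological age groups with
#' rank-biserial effect size; (3) the same comparison between younger
#' (<= 65 y) and older (>= 80 y) chronological groups; and (4) CU-cohort
#' null checks (mean composite w-scores, CoMeT-BAG correlation).
#' Comparisons with fewer than two subjects in a group are reported as
#' not computable rather than failing.
#'
#' @param comet_results [compute_comet()] output.
#' @param bag_results [compute_bag_table()] output.
#' @param cohort_labels [assign_cohort()] output.
#' @param participants participant table (`id`, `age_at_mri`,
#'   `diagnosis`).
#' @return An object of class `comet_analysis`: `table` (one row per
#'   statistic) and `cu_w_means` (named CU means of cortical/MTL
#'   w-scores and CoMeT).
#' @export
run_primary_analysis <- function(comet_results, bag_results, cohort_labels,
                                 participants) {
  d <- merge(comet_results, cohort_labels, by = "participant_id")
  d <- merge(d, participants[, c("id", "age_at_mri", "diagnosis")],
             by.x = "participant_id", by.y = "id")
  d <- merge(d,
             bag_results[, c("participant_id", "bag", "bio_age_group")],
             by = "participant_id", all.x = TRUE)
  d$chron_group <- age_group(d$age_at_mri)

  sym <- d[d$cohort == "symptomatic", , drop = FALSE]
  dem <- sym[sym$diagnosis == "dementia", , drop = FALSE]
  cu <- d[d$cohort == "CU", , drop = FALSE]

  with_bag <- function(x) x[!is.na(x$bag), , drop = FALSE]

  rows <- list()
  for (set in list(list(sym, "symptomatic"), list(dem, "dementia"),
                   list(cu, "CU"))) {
    dd <- set[[1]]
    coh <- set[[2]]
    db <- with_bag(dd)
    rows <- c(rows, list(
      comet_bag_cor_row(db, coh),
      comet_group_row(db, db$bio_age_group, "decelerated", "accelerated",
                      "wilcoxon_comet_decel_vs_accel", coh),
      comet_group_row(dd, dd$chron_group, "younger", "older",
                      "wilcoxon_comet_younger_vs_older", coh)
    ))
  }
  tab <- do.call(rbind, rows)

  cu_w_means <- c(cortical_w = mean(cu$cortical_w),
                  mtl_w = mean(cu$mtl_w),
                  comet = mean(cu$comet))

  structure(list(table = tab, cu_w_means = cu_w_means,
                 n = c(symptomatic = nrow(sym), dementia = nrow(dem),
                       CU = nrow(cu))),
            class = "comet_analysis")
}

#' @export
print.comet_analysis <- function(x, ...) {
  cat("CoMeT primary analysis\n")
  cat(sprintf("  cohorts: symptomatic n = %d (dementia %d), CU n = %d\n",
              x$n["symptomatic"], x$n["dementia"], x$n["CU"]))
  cat(sprintf("  CU mean w-scores: cortical %.2e, MTL %.2e, CoMeT %.2e\n",
              x$cu_w_means["cortical_w"], x$cu_w_means["mtl_w"],
              x$cu_w_means["comet"]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Human-readable analysis summary
#'
#' @param analysis a `comet_analysis`.
#' @return Character vector of report lines.
#' @export
format_analysis_summary <- function(analysis) {
  tab <- analysis$table
  lines <- c("CoMeT / biological age analysis report", "")
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    lines <- c(lines, if (nzchar(r$note)) {
      sprintf("%-32s [%s]  %s", r$analysis, r$cohort, r$note)
    } else if (startsWith(r$analysis, "pearson")) {
      sprintf("%-32s [%s]  n=%d, r=%.3f, p=%.4g",
              r$analysis, r$cohort, r$n_a, r$estimate, r$p_value)
    } else {
      sprintf("%-32s [%s]  n=(%d,%d), W=%g, rank-biserial=%.3f, p=%.4g",
              r$analysis, r$cohort, r$n_a, r$n_b, r$statistic, r$estimate,
              r$p_value)
    })
  }
  c(lines, "",
    sprintf("CU mean w-scores: cortical %.3e, MTL %.3e, CoMeT %.3e",
            analysis$cu_w_means["cortical_w"], analysis$cu_w_means["mtl_w"],
            analysis$cu_w_means["comet"]))
}
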