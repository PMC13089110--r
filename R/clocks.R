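# Linear epigenetic clocks and biological age gap (BAG) computation.
#
# A clock is a linear predictor over CpG beta values, optionally followed
# by the adult/log age anti-transform used by paediatric-calibrated clocks.
# BAG is the residual from regressing clock-predicted age on chronological
# age over a named cohort; per-clock BAGs are averaged to damp clock-
# specific noise.

#' Construct a linear epigenetic clock model
#'
#' @param name clock name.
#' @param intercept intercept, in transformed-age units.
#' @param coefficients named numeric vector of CpG weights (names are CpG
#'   ids; non-empty, unique).
#' @param transform `"identity"` (the linear predictor is the age in
#'   years) or `"log_linear_adult"` (the predictor is on a log scale below
#'   `adult_age` and linear above; see [age_anti_transform()]).
#' @param adult_age transition age in years for the log-linear transform.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        transform = c("identity", "log_linear_adult"),
                        adult_age = 20) {
  transform <- match.arg(transform)
  if (length(coefficients) == 0 || is.null(names(coefficients)) ||
      anyDuplicated(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    cb_stop("clock coefficients must be a non-empty, uniquely named vector",
            "cometbag_input_error")
  }
  if (adult_age <= 0) cb_stop("adult_age must be > 0", "cometbag_input_error")
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, transform = transform,
                 adult_age = adult_age),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d CpGs, transform %s\n",
              x$name, length(x$coefficients), x$transform))
  invisible(x)
}

#' Age transform and anti-transform for log-linear adult clocks
#'
#' Maps chronological age to the transformed scale on which such clocks
#' are linear: `log(age + 1) - log(adult_age + 1)` up to `adult_age`,
#' linear `(age - adult_age) / (adult_age + 1)` above.  The
#' anti-transform inverts it: `(adult_age + 1) * exp(m) - 1` for `m < 0`,
#' `adult_age + m * (adult_age + 1)` otherwise, with fixed point
#' `age = adult_age` at `m = 0`.
#'
#' @param age,m numeric vectors (years / transformed units).
#' @param adult_age transition age, years.
#' @return Numeric vector.
#' @export
age_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @export
age_anti_transform <- function(m, adult_age = 20) {
  ifelse(m < 0, (adult_age + 1) * exp(m) - 1, adult_age + m * (adult_age + 1))
}

#' Predict age from methylation betas with a clock
#'
#' Computes the linear predictor `intercept + sum(coef * beta)` per row of
#' the matrix and applies the clock's anti-transform.  Every clock CpG
#' must be present; missing CpGs are an error (no silent imputation).
#'
#' @param betas methylation matrix (rows = participants or replicates,
#'   columns = CpG ids, values in \[0, 1\]).
#' @param clock a [clock_model()].
#' @return Named numeric vector of predicted ages in years.
#' @export
apply_clock <- function(betas, clock) {
  stopifnot(inherits(clock, "clock_model"))
  cpgs <- names(clock$coefficients)
  missing <- setdiff(cpgs, colnames(betas))
  if (length(missing) > 0) {
    cb_stop(paste0("clock `", clock$name, "` CpGs missing from matrix: ",
                   paste(missing, collapse = ", ")),
            "cometbag_input_error")
  }
  m <- drop(betas[, cpgs, drop = FALSE] %*% clock$coefficients) + clock$intercept
  pred <- switch(clock$transform,
                 identity = m,
                 log_linear_adult = age_anti_transform(m, clock$adult_age))
  names(pred) <- rownames(betas)
  pred
}

#' Keep one methylation replicate per participant
#'
#' Rows of a methylation matrix are keyed by participant id, with
#' technical replicates suffixed `_r<k>`.  For each participant with
#' several rows one is selected uniformly at random; the choice is
#' deterministic under `seed`.
#'
#' @param betas methylation matrix with rownames `id` or `id_r<k>`.
#' @param seed integer seed for the selection.
#' @return The matrix restricted to one row per participant, rownames
#'   reset to bare participant ids, original participant order kept.
#' @export
select_replicate <- function(betas, seed = 1L) {
  pid <- sub("_r[0-9]+$", "", rownames(betas))
  set.seed(seed)
  keep <- integer(0)
  for (p in unique(pid)) {
    idx <- which(pid == p)
    keep <- c(keep, if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)])
  }
  out <- betas[keep, , drop = FALSE]
  rownames(out) <- pid[keep]
  out
}

#' Biological age gap: residuals of predicted on chronological age
#'
#' Ordinary least squares of clock-predicted age on chronological age
#' (intercept + slope), fitted over the supplied cohort; the residuals
#' are the per-clock biological age gaps.  By construction they sum to
#' zero and are uncorrelated with chronological age over that cohort.
#' No covariates are adjusted for at this stage.
#'
#' @param predicted named numeric vector of predicted ages, years.
#' @param chronological numeric vector of chronological ages, years,
#'   aligned with `predicted`.
#' @return Named numeric vector of residuals (years).
#' @export
compute_bag <- function(predicted, chronological) {
  if (length(predicted) != length(chronological) || length(predicted) < 3) {
    cb_stop("need >= 3 aligned (predicted, chronological) pairs",
            "cometbag_estimation_error")
  }
  if (stats::sd(chronological) == 0) {
    cb_stop("chronological ages are constant; BAG regression is degenerate",
            "cometbag_estimation_error")
  }
  fit <- stats::lm(predicted ~ chronological)
  res <- stats::residuals(fit)
  names(res) <- names(predicted)
  res
}

#' Average per-clock BAG residuals
#'
#' @param per_clock_residuals named list of residual vectors, one per
#'   clock, all named by the same participants.
#' @return Numeric vector: element-wise mean, participant order of the
#'   first clock preserved.
#' @export
average_bag <- function(per_clock_residuals) {
  stopifnot(is.list(per_clock_residuals), length(per_clock_residuals) >= 1)
  ref <- names(per_clock_residuals[[1]])
  mats <- lapply(per_clock_residuals, function(v) {
    if (is.null(names(v)) || !setequal(names(v), ref) ||
        length(v) != length(ref)) {
      cb_stop("per-clock residual vectors are not aligned on the same participants",
              "cometbag_alignment_error")
    }
    v[ref]
  })
  out <- rowMeans(do.call(cbind, mats))
  names(out) <- ref
  out
}

#' Stratify a BAG vector into biological age groups
#'
#' Standardizes the BAG over the supplied cohort (sample SD, denominator
#' n - 1) and assigns `accelerated` for z >= +k, `decelerated` for
#' z <= -k, `neutral` otherwise.  The boundary |z| = k is assigned to the
#' extreme groups.
#'
#' @param bag numeric BAG vector (years).
#' @param k SD multiplier, default 0.5.
#' @return Factor with levels decelerated, neutral, accelerated, named as
#'   `bag`.
#' @export
stratify_bag <- function(bag, k = 0.5) {
  if (length(bag) < 2 || stats::sd(bag) == 0) {
    cb_stop("BAG stratification needs >= 2 participants with nonzero SD",
            "cometbag_stratification_error")
  }
  z <- (bag - mean(bag)) / stats::sd(bag)
  out <- factor(ifelse(z >= k, "accelerated",
                       ifelse(z <= -k, "decelerated", "neutral")),
                levels = c("decelerated", "neutral", "accelerated"))
  names(out) <- names(bag)
  out
}

#' Full per-participant BAG table from a methylation matrix
#'
#' Convenience wrapper: selects one replicate per participant, applies
#' each clock, computes per-clock regression BAGs over the supplied
#' cohort, averages them, and stratifies into biological age groups.
#'
#' @param betas methylation matrix (may contain technical replicates).
#' @param clocks list of [clock_model()]s.
#' @param ages named numeric vector of chronological ages (years) for at
#'   least all participants in `betas`.
#' @param k SD multiplier for [stratify_bag()].
#' @param seed seed for replicate selection.
#' @return A data.frame (one row per participant): `participant_id`,
#'   `age`, per-clock `predicted_*` and `bag_*` columns, averaged `bag`,
#'   and `bio_age_group`.
#' @export
compute_bag_table <- function(betas, clocks, ages, k = 0.5, seed = 1L) {
  betas <- select_replicate(betas, seed = seed)
  pid <- rownames(betas)
  missing <- setdiff(pid, names(ages))
  if (length(missing) > 0) {
    cb_stop(paste("chronological age missing for:",
                  paste(utils::head(missing, 5), collapse = ", ")),
            "cometbag_alignment_error")
  }
  chron <- ages[pid]
  preds <- lapply(clocks, function(cl) apply_clock(betas, cl))
  resids <- lapply(preds, function(p) compute_bag(p, chron))
  names(preds) <- names(resids) <- vapply(clocks, `[[`, "", "name")
  bag <- average_bag(resids)
  out <- data.frame(participant_id = pid, age = as.numeric(chron),
                    stringsAsFactors = FALSE)
  for (nm in names(preds)) {
    out[[paste0("predicted_", nm)]] <- as.numeric(preds[[nm]])
    out[[paste0("bag_", nm)]] <- as.numeric(resids[[nm]])
  }
  out$bag <- as.numeric(bag)
  out$bio_age_group <- as.character(stratify_bag(bag, k = k))
  out
}

#' Read / write clock coefficient files
#'
#' The on-disk format is a CSV with columns `CpG_id`, `coefficient`, an
#' `(Intercept)` row, and a header block of comment lines declaring the
#' clock name, transform and adult age, e.g.:
#' \preformatted{# clock: Horvath2013
#' # transform: log_linear_adult
#' # adult_age: 20
#' CpG_id,coefficient
#' (Intercept),0.696
#' cg00000292,0.0512}
#' Published clock coefficients in this layout can be dropped in; none
#' are bundled.
#'
#' @param path file path.
#' @param clock a [clock_model()] (for writing).
#' @return `read_clock_model()` returns a [clock_model()].
#' @export
read_clock_model <- function(path) {
  if (!file.exists(path)) {
    cb_stop(paste("clock file not found:", path), "cometbag_input_error")
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key, default = NULL) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  int_row <- tab$CpG_id == "(Intercept)"
  coefs <- tab$coefficient[!int_row]
  names(coefs) <- tab$CpG_id[!int_row]
  clock_model(
    name = field("clock", basename(path)),
    intercept = if (any(int_row)) tab$coefficient[int_row][1] else 0,
    coefficients = coefs,
    transform = field("transform", "identity"),
    adult_age = as.numeric(field("adult_age", "20"))
  )
}

#' @rdname read_clock_model
#' @export
write_clock_model <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# clock:", clock$name),
    paste("# transform:", clock$transform),
    paste("# adult_age:", format(clock$adult_age)),
    "CpG_id,coefficient",
    paste0("(Intercept),", format(clock$intercept, digits = 17)),
    paste0(names(clock$coefficients), ",",
           format(clock$coefficients, digits = 17, trim = TRUE))
  ), con)
  invisible(path)
}
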