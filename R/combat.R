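# Reference-fitted parametric empirical-Bayes ComBat.
#
# Location/scale batch harmonization: per feature, a least-squares fit of
# the value on biological covariates plus batch indicators; residuals are
# standardized by the pooled residual SD; per-batch location and scale
# estimates are shrunk toward parametric priors (normal for location,
# inverse-gamma for scale) with moment-matched hyperparameters, via
# iterative conditional posterior updates.  The fitted model can be
# applied to rows not seen at fit time (here: fit on the cognitively
# unimpaired reference, applied to symptomatic subjects), which is the
# reason ComBat is re-authored here rather than called from an existing
# implementation that only transforms its own training data.  Biological
# covariate contributions are added back unchanged, so age, sex and
# diagnosis effects are preserved.
#
# Numerics follow the standard parametric ComBat algorithm: pooled
# variance with denominator n, per-batch scale estimates with denominator
# n_b - 1, EB iteration tolerance 1e-4 on the relative change of
# successive location/scale updates, at most 1000 iterations.

# -- covariate encoding -------------------------------------------------

# Encode a covariate data.frame as a numeric design block with recorded
# template so unseen rows are encoded identically: numeric columns as-is,
# sex as male=0/female=1, other factors one-hot with the first fit-time
# level as baseline.  Constant columns are dropped at fit (e.g. diagnosis
# when fitting on CU only) and recorded.
encode_covariates <- function(covariates, template = NULL) {
  if (is.null(covariates) || ncol(covariates) == 0) {
    return(list(mat = matrix(numeric(0), nrow = NROW(covariates), ncol = 0),
                template = list(columns = list(), kept = character(0))))
  }
  if (is.null(template)) {
    columns <- lapply(names(covariates), function(nm) {
      x <- covariates[[nm]]
      if (is.numeric(x)) {
        list(name = nm, type = "numeric")
      } else if (nm == "sex" || setequal(unique(as.character(x)), c("female", "male")) ||
                 all(as.character(x) %in% c("female", "male"))) {
        list(name = nm, type = "sex")
      } else {
        list(name = nm, type = "factor", levels = sort(unique(as.character(x))))
      }
    })
    names(columns) <- names(covariates)
    template <- list(columns = columns, kept = NULL)
  }
  encode_one <- function(col, check_levels) {
    x <- covariates[[col$name]]
    if (is.null(x)) {
      cb_stop(paste("covariate column missing:", col$name),
              "cometbag_input_error")
    }
    switch(col$type,
      numeric = {
        m <- matrix(as.numeric(x), ncol = 1)
        colnames(m) <- col$name
        m
      },
      sex = {
        m <- matrix(as.numeric(as.character(x) == "female"), ncol = 1)
        colnames(m) <- col$name
        m
      },
      factor = {
        x <- as.character(x)
        if (check_levels) {
          unseen <- setdiff(unique(x), col$levels)
          if (length(unseen) > 0) {
            cb_stop(paste0("unseen level(s) in covariate `", col$name, "`: ",
                           paste(unseen, collapse = ", ")),
                    "cometbag_input_error")
          }
        }
        lev <- col$levels[-1]
        if (length(lev) == 0) {
          return(matrix(numeric(0), nrow = length(x), ncol = 0))
        }
        m <- matrix(vapply(lev, function(l) as.numeric(x == l),
                           numeric(length(x))), nrow = length(x))
        colnames(m) <- paste0(col$name, lev)
        m
      })
  }

  fitting <- is.null(template$kept)
  blocks <- lapply(template$columns, function(col) {
    block_names <- switch(col$type,
                          numeric = col$name, sex = col$name,
                          factor = paste0(col$name, col$levels[-1]))
    # a column whose encoded block was dropped entirely at fit (e.g. a
    # constant diagnosis in a CU-only reference) is skipped at apply
    # time, so unseen levels in it are irrelevant
    active <- fitting || any(block_names %in% template$kept)
    if (!active) return(matrix(numeric(0), nrow = NROW(covariates), ncol = 0))
    encode_one(col, check_levels = !fitting)
  })
  mat <- do.call(cbind, c(blocks, list(deparse.level = 0)))
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = NROW(covariates), ncol = 0)
  if (fitting) {
    keep <- if (ncol(mat) > 0) apply(mat, 2, function(v) stats::sd(v) > 0) else logical(0)
    template$kept <- colnames(mat)[keep]
  }
  list(mat = mat[, template$kept, drop = FALSE], template = template)
}

as_feature_matrix <- function(data) {
  if (is.data.frame(data)) {
    num <- vapply(data, is.numeric, TRUE)
    data <- as.matrix(data[, num, drop = FALSE])
  }
  storage.mode(data) <- "double"
  data
}

# -- fitting -------------------------------------------------------------

#' Fit a ComBat harmonization model on a reference cohort
#'
#' @param reference samples-by-features numeric matrix (or data.frame;
#'   non-numeric columns are dropped) of ROI measures for the reference
#'   cohort, e.g. all cognitively unimpaired subjects.
#' @param covariates data.frame of biological covariates for the same
#'   rows (typically age, sex, and diagnosis when cohorts are mixed);
#'   constant columns are dropped with a message.
#' @param batch vector of batch labels per row (e.g. scanner field
#'   strength); every batch needs at least 2 reference rows.
#' @return An object of class `combat_model` storing the standardization
#'   fit (batch-specific intercepts, covariate coefficients, pooled
#'   residual variance) and the EB-shrunken per-batch location
#'   (`gamma_star`) and scale (`delta_star`) parameters.
#' @seealso [apply_combat()]
#' @export
fit_combat <- function(reference, covariates, batch) {
  dat <- as_feature_matrix(reference)
  batch <- as.character(batch)
  if (length(batch) != nrow(dat)) {
    cb_stop("batch labels must match reference rows", "cometbag_fit_error")
  }
  levels <- sort(unique(batch))
  counts <- table(factor(batch, levels = levels))
  if (length(levels) < 2) {
    cb_stop("ComBat needs at least 2 batches in the reference",
            "cometbag_fit_error")
  }
  if (any(counts < 2)) {
    cb_stop(paste("each batch needs >= 2 reference rows; too small:",
                  paste(levels[counts < 2], collapse = ", ")),
            "cometbag_fit_error")
  }

  enc <- encode_covariates(covariates, template = NULL)
  dropped <- setdiff(colnames(enc$mat), enc$template$kept)

  batch_design <- sapply(levels, function(l) as.numeric(batch == l))
  design <- cbind(batch_design, enc$mat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    cb_stop("singular design: batch indicators and covariates are confounded",
            "cometbag_fit_error")
  }

  n <- nrow(dat)
  p <- ncol(dat)
  n_batches <- as.numeric(counts)

  B_hat <- solve(crossprod(design), crossprod(design, dat))
  batch_means <- B_hat[seq_along(levels), , drop = FALSE]       # batches x features
  cov_coef <- B_hat[-seq_along(levels), , drop = FALSE]          # covs x features
  grand_mean <- drop(crossprod(n_batches / n, batch_means))      # features
  var_pooled <- colSums((dat - design %*% B_hat)^2) / n          # MLE denominator

  if (any(var_pooled <= 0)) {
    cb_stop("zero pooled residual variance; cannot standardize",
            "cometbag_fit_error")
  }

  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE) + enc$mat %*% cov_coef
  s_data <- (dat - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_hat <- rowsum(s_data, batch)[levels, , drop = FALSE] / n_batches
  delta_hat <- t(vapply(levels, function(l) {
    apply(s_data[batch == l, , drop = FALSE], 2, stats::var)
  }, numeric(p)))
  if (p == 1) delta_hat <- matrix(delta_hat, ncol = 1)
  dimnames(gamma_hat) <- dimnames(delta_hat) <- list(levels, colnames(dat))

  if (p >= 2) {
    gamma_bar <- rowMeans(gamma_hat)
    t2 <- apply(gamma_hat, 1, stats::var)
    m_d <- rowMeans(delta_hat)
    s2_d <- apply(delta_hat, 1, stats::var)
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d

    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (i in seq_along(levels)) {
      sdat <- s_data[batch == levels[i], , drop = FALSE]
      sol <- eb_iterate(sdat, gamma_hat[i, ], delta_hat[i, ],
                        gamma_bar[i], t2[i], a_prior[i], b_prior[i])
      gamma_star[i, ] <- sol$gamma
      delta_star[i, ] <- sol$delta
    }
  } else {
    # moment-matched priors need >= 2 features; fall back to the
    # unshrunken per-batch estimates
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  structure(list(
    features = colnames(dat),
    batches = levels,
    batch_n = n_batches,
    cov_template = enc$template,
    dropped_covariates = dropped,
    cov_coef = cov_coef,
    grand_mean = grand_mean,
    var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star
  ), class = "combat_model")
}

# iterative conditional posterior updates for one batch (parametric EB);
# relative-change convergence at 1e-4, as in standard parametric ComBat
eb_iterate <- function(sdat, g_hat, d_hat, g_bar, t2, a, b,
                       conv = 1e-4, maxit = 1000L) {
  nb <- nrow(sdat)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- (t2 * nb * g_hat + d_old * g_bar) / (t2 * nb + d_old)
    sum2 <- colSums((sdat - matrix(g_new, nb, length(g_new), byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b) / (nb / 2 + a - 1)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_new, delta = d_new)
}

#' Apply a fitted ComBat model to (possibly unseen) rows
#'
#' Standardizes each row with the stored covariate fit and pooled
#' variance, removes the EB-shrunken batch location, rescales by the
#' batch scale, and de-standardizes, adding covariate contributions back
#' unchanged.
#'
#' @param model a [fit_combat()] model.
#' @param data samples-by-features matrix/data.frame with the fitted
#'   feature columns.
#' @param covariates covariate data.frame for these rows (same columns as
#'   at fit).
#' @param batch batch label per row; must have been seen at fit.
#' @return The harmonized data, same shape and type layout as `data`.
#' @export
apply_combat <- function(model, data, covariates, batch) {
  stopifnot(inherits(model, "combat_model"))
  dat_full <- data
  dat <- as_feature_matrix(data)
  missing <- setdiff(model$features, colnames(dat))
  if (length(missing) > 0) {
    cb_stop(paste("features missing from data:", paste(missing, collapse = ", ")),
            "cometbag_application_error")
  }
  dat <- dat[, model$features, drop = FALSE]
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen) > 0) {
    cb_stop(paste("batch label(s) not seen at fit:", paste(unseen, collapse = ", ")),
            "cometbag_application_error")
  }
  enc <- encode_covariates(covariates, template = model$cov_template)

  n <- nrow(dat)
  p <- length(model$features)
  stand_mean <- matrix(model$grand_mean, n, p, byrow = TRUE) +
    enc$mat %*% model$cov_coef
  z <- (dat - stand_mean) / matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  bi <- match(batch, model$batches)
  z_adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  out <- z_adj * matrix(sqrt(model$var_pooled), n, p, byrow = TRUE) + stand_mean

  if (is.data.frame(dat_full)) {
    for (f in model$features) dat_full[[f]] <- out[, f]
    dat_full
  } else {
    out
  }
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, batches: %s (n = %s)\n",
              length(x$features), paste(x$batches, collapse = ", "),
              paste(x$batch_n, collapse = ", ")))
  if (length(x$dropped_covariates) > 0) {
    cat("  dropped constant covariate column(s):",
        paste(x$dropped_covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore a ComBat model
#'
#' Writes the model as JSON with exact-precision floats.
#'
#' @param model a `combat_model`.
#' @param path file path.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  x <- unclass(model)
  x$gamma_hat <- as.data.frame(x$gamma_hat)
  x$delta_hat <- as.data.frame(x$delta_hat)
  x$gamma_star <- as.data.frame(x$gamma_star)
  x$delta_star <- as.data.frame(x$delta_star)
  x$cov_coef <- as.data.frame(x$cov_coef)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gamma_hat", "delta_hat", "gamma_star", "delta_star", "cov_coef")) {
    x[[f]] <- as.matrix(x[[f]])
    if (f != "cov_coef") rownames(x[[f]]) <- x$batches
  }
  x$grand_mean <- stats::setNames(as.numeric(x$grand_mean), x$features)
  x$var_pooled <- stats::setNames(as.numeric(x$var_pooled), x$features)
  # restore template structure
  x$cov_template$columns <- lapply(x$cov_template$columns, function(col) col)
  structure(x, class = "combat_model")
}
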