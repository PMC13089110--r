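# CSV/JSON input-output for the pipeline tables.  All tables are UTF-8
# CSV with a header row; the methylation matrix stores its row key
# (participant id, optionally with a replicate suffix) in the first
# column `row_id`.

#' Write / read a pipeline table
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    cb_stop(paste("table not found:", path), "cometbag_input_error")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a methylation beta matrix
#'
#' @param betas numeric matrix, rows = participants (or replicates),
#'   columns = CpG ids.
#' @param path CSV path.
#' @export
write_methylation <- function(betas, path) {
  df <- data.frame(row_id = rownames(betas), betas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path) {
  df <- read_table(path)
  m <- as.matrix(df[, setdiff(names(df), "row_id"), drop = FALSE])
  rownames(m) <- df$row_id
  storage.mode(m) <- "double"
  m
}

#' Write / read the generator's ground-truth record as JSON
#'
#' The truth record is sufficient to check every planted parameter
#' without re-running the generator.
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$clocks <- lapply(x$clocks, function(cl) {
    list(name = cl$name, intercept = cl$intercept,
         coefficients = as.list(cl$coefficients),
         transform = cl$transform, adult_age = cl$adult_age)
  })
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$clocks) && length(x$clocks) > 0) {
    # jsonlite simplifies the clock list to a data.frame whose
    # `coefficients` column is itself a data.frame over the union of all
    # CpG ids (NA where a clock does not use a CpG)
    x$clocks <- lapply(seq_len(nrow(x$clocks)), function(i) {
      coefs <- unlist(x$clocks$coefficients[i, , drop = FALSE])
      coefs <- coefs[!is.na(coefs)]
      clock_model(name = x$clocks$name[i], intercept = x$clocks$intercept[i],
                  coefficients = coefs, transform = x$clocks$transform[i],
                  adult_age = x$clocks$adult_age[i])
    })
  } else {
    x$clocks <- NULL
  }
  structure(x, class = "synthetic_truth")
}
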