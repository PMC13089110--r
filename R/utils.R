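#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single top-level integer seed.
#' Each table or stage draws from its own sub-stream, derived
#' deterministically from the top-level seed and a stream label, so that
#' adding a new table to the generator does not perturb draws for earlier
#' tables.
#'
#' @param seed integer top-level seed.
#' @param label character stream label (e.g. `"roi"`).
#' @return An integer seed below 2^31, suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483563  # large prime below 2^31; double arithmetic stays exact
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((h + (seed %% m) * 40503) %% m)
}

# stop() with a class so callers/tests can distinguish error kinds
cb_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cometbag_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

check_number <- function(x, field, lower = -Inf, upper = Inf, len = 1,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) ||
      any(x < lower) || any(x > upper) ||
      (integer && any(x != round(x)))) {
    cb_stop(sprintf("invalid configuration field `%s`", field),
            "cometbag_config_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
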