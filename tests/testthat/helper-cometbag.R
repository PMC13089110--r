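# Shared fixtures and independent oracles for the test suite.

# small, fast cohort for smoke-level tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_cu = 60, n_mci = 30, n_dementia = 30, seed = seed, ...)
}

# DNAm-subset scale of the study population
dnam_scale_config <- function(seed = 1, ...) {
  synthetic_config(n_cu = 163, n_mci = 170, n_dementia = 115, seed = seed, ...)
}

# brute-force pairwise-dominance oracle for the rank-biserial correlation
brute_rank_biserial <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + sign(x - y)
  s / (length(a) * length(b))
}

# closed-form simple linear regression residuals (independent of lm)
ols_residuals_oracle <- function(y, x) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  y - alpha - beta * x
}

# exact rank-sum distribution by enumeration over combinations
exact_ranksum_pvalues <- function(na, nb) {
  N <- na + nb
  sets <- utils::combn(N, na)
  sums <- colSums(matrix(seq_len(N)[sets], nrow = na))
  list(values = sort(unique(sums)),
       prob = as.numeric(table(sums)) / ncol(sets))
}

with_quiet_pipeline <- function(expr) suppressMessages(expr)
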