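# Independent oracles, written from first principles so they never share
# code with the implementation they check.

# Two-sided Fisher exact p by direct hypergeometric enumeration over all
# 2x2 tables with the observed margins (sum of point probabilities not
# exceeding the observed one).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[xs == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Pooled-variance two-sided t-test from the textbook formula.
ttest_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Closed-form simple-regression coefficients.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = b, intercept = mean(y) - b * mean(x))
}

# Random A/C/G/T string.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Shared default fragment for primer tests (deterministic).
ins2_test_fragment <- local({
  frag <- NULL
  function() {
    if (is.null(frag)) frag <<- make_fragment(ins2_fragment_spec(), seed = 1L)
    frag
  }
})
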