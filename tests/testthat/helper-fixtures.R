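# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# Small cohort: fast enough for per-module tests.
tiny_cfg <- function(...) {
  synth_config(n_random = 150, n_oversampled = 350, n_snps = 25,
               n_metabolites = 12, seed = 99, ...)
}

tiny_sim <- function() {
  memo("tiny_sim", suppressWarnings(simulate_cohort(tiny_cfg(), inject = FALSE)))
}

# Mid-size cohort (n = 2000) for properties needing statistical resolution.
mid_sim <- function() {
  memo("mid_sim", suppressWarnings(simulate_cohort(
    synth_config(n_random = 500, n_oversampled = 1500, n_snps = 40,
                 n_metabolites = 16, n_classes = 4, seed = 2024),
    inject = FALSE)))
}

# Independent numeric oracle for the Deming fit: minimize the weighted
# orthogonal loss sum((y - a - b x)^2) / (lambda + b^2). The intercept is
# profiled out exactly (a = ybar - b xbar); the slope is found by golden
# section on the side of zero where the loss minimum lives (the two critical
# points of the profiled loss have opposite signs, product -lambda).
deming_numeric_oracle <- function(x, y, lambda = 1) {
  g <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2) / (lambda + b^2)
  }
  side <- sign(sum((x - mean(x)) * (y - mean(y))))
  interval <- if (side >= 0) c(1e-8, 1e4) else c(-1e4, -1e-8)
  b <- stats::optimize(g, interval, tol = 1e-12)$minimum
  list(intercept = mean(y) - b * mean(x), slope = b)
}
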