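# shared fixture calls, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    .fixture_env$calls <- call_cases(example_cases())
  }
  .fixture_env$calls
}

# closed-form Pearson chi-square oracle for a 2x2 table (independent of the
# implementation, which goes through stats::chisq.test)
chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

strip_raw <- function(k) {
  k$raw <- NULL
  k
}
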