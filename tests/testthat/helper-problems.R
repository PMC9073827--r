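# Printed tables report 3 decimal places; compare at half a unit in the last
# printed place (plus a double-rounding guard).
expect_printed <- function(actual, printed, tol = 5e-4) {
  expect_true(all(abs(actual - printed) <= tol + 1e-12),
              label = sprintf("max deviation %.3g from printed value(s)",
                              max(abs(actual - printed))))
}

# Random valid interval pair on a modest scale, for property sweeps.
random_interval <- function(scale = 100) {
  a <- stats::runif(2, -scale, scale)
  sort(a)
}

# The packaged worked problem, shared across test files.
we <- worked_example()
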