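test_that("value function is piecewise power with loss aversion", {
  pars <- cpt_params()                     # alpha = beta = 1, lambda = 2
  expect_equal(pt_value(-0.120, pars), -0.240)
  expect_equal(pt_value(0, pars), 0)
  expect_equal(pt_value(15.988, pars), 15.988)
  curved <- cpt_params(alpha = 0.88, beta = 0.88, lambda = 2.25)
  expect_equal(pt_value(4, curved), 4^0.88)
  expect_equal(pt_value(-4, curved), -2.25 * 4^0.88)
  # strictly increasing; |v(-z)| = lambda v(z) for z > 0 when alpha = beta
  z <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(pt_value(z, curved)) > 0))
  zp <- z[z > 0]
  expect_equal(abs(pt_value(-zp, curved)), 2.25 * pt_value(zp, curved))
})

test_that("cpt_params validates parameter ranges", {
  expect_error(cpt_params(alpha = 0), "alpha")
  expect_error(cpt_params(alpha = 1.2), "alpha")
  expect_error(cpt_params(lambda = 0.5), "lambda")
  expect_error(cpt_params(mu = 0), "mu")
})

test_that("neo-additive weighting matches its closed form and identities", {
  expect_equal(probability_weight(0.75, 0.6), 0.65)
  expect_equal(probability_weight(0.3, 0.6), 0.38)
  expect_identical(probability_weight(1, 0.6), 1)
  expect_identical(probability_weight(0, 0.6), 0)
  expect_error(probability_weight(1.1), "\\[0, 1\\]")
  for (mu in c(0.1, 0.45, 0.6, 1)) {
    p <- seq(0, 1, by = 0.05)
    expect_equal(probability_weight(p, mu) + probability_weight(1 - p, mu),
                 rep(1, length(p)))
    expect_true(all(diff(probability_weight(p, mu)) >= 0))
  }
  expect_equal(probability_weight(c(0.2, 0.5, 0.9), 1), c(0.2, 0.5, 0.9))
})

test_that("two-outcome decision weights match the printed transition weights", {
  expect_equal(as.numeric(decision_weights(c(0.75, 0.25), c(0.725, -0.613))),
               c(0.65, 0.35))
  expect_equal(as.numeric(decision_weights(c(0.8, 0.2), c(0.752, -0.252))),
               c(0.68, 0.32))
  expect_equal(as.numeric(decision_weights(c(0.7, 0.3), c(0.931, -0.408))),
               c(0.62, 0.38))
  expect_error(decision_weights(c(0.7, 0.2), c(1, -1)), "sum to")
})

test_that("decision weights telescope to a total of one for any prospect", {
  # oracle: build each pi from explicit cumulative enumerations, then compare
  brute_force_pi <- function(p, v, mu) {
    ord <- order(-v, seq_along(v))
    ps <- p[ord]; vs <- v[ord]
    m <- sum(vs >= 0); N <- length(p)
    # same endpoint contract as the implementation: an accumulated
    # probability within 1e-9 of 1 is the full prospect
    w <- function(x) probability_weight(ifelse(abs(x - 1) <= 1e-9, 1, x), mu)
    pis <- numeric(N)
    for (j in seq_len(N)) {
      if (j <= m) pis[j] <- w(sum(ps[seq_len(j)])) - w(sum(ps[seq_len(j - 1)]))
      else pis[j] <- w(sum(ps[j:N])) - w(if (j < N) sum(ps[(j + 1):N]) else 0)
    }
    out <- numeric(N); out[ord] <- pis
    out
  }
  set.seed(17)
  for (i in 1:200) {
    N <- sample(1:5, 1)
    p <- rexp(N); p <- p / sum(p)
    v <- runif(N, -1, 1)
    mu <- runif(1, 0.05, 1)
    pi <- decision_weights(p, v, cpt_params(mu = mu))
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_equal(as.numeric(pi), brute_force_pi(p, v, mu), tolerance = 1e-12)
  }
})

test_that("mu = 1 reduces two-outcome decision weights to the probabilities", {
  pi <- decision_weights(c(0.7, 0.3), c(0.4, -0.2), cpt_params(mu = 1))
  expect_equal(as.numeric(pi), c(0.7, 0.3))
  pi <- decision_weights(c(0.7, 0.3), c(0.4, -0.2), identity_weighting = TRUE)
  expect_equal(as.numeric(pi), c(0.7, 0.3))
})

test_that("zero-valued outcomes rank with the gains and ties keep input order", {
  pi <- decision_weights(c(0.5, 0.3, 0.2), c(0.4, 0, -0.1))
  expect_equal(attr(pi, "is_gain"), c(TRUE, TRUE, FALSE))
  # equal values: stable order means the earlier outcome keeps the better rank
  pi2 <- decision_weights(c(0.6, 0.4), c(0.5, 0.5))
  w <- function(x) probability_weight(x, 0.6)
  expect_equal(as.numeric(pi2), c(w(0.6), w(1) - w(0.6)))
})

test_that("per-criterion normalization scales by the max absolute value", {
  v <- cbind(c(15.988, -15.476, 23.488), c(0.2, -0.1, 0))
  vt <- normalize_values(v)
  expect_equal(attr(vt, "v_star"), c(23.488, 0.2))
  expect_equal(max(abs(vt[, 1])), 1)
  expect_true(all(abs(vt) <= 1))
  # an all-zero criterion stays all-zero
  vt0 <- normalize_values(cbind(c(1, -2), c(0, 0)))
  expect_equal(unname(vt0[, 2]), c(0, 0))
  # ratio invariance: rescaling one criterion's values leaves vtilde unchanged
  expect_equal(unname(normalize_values(v * 3)[, 1]), unname(vt[, 1]))
})

test_that("prospect value collapses to the per-outcome combined form for uniform signs", {
  # when an outcome has the same sign on every criterion, weighting the
  # combined normalized value per outcome equals the per-attribute formula
  vt <- rbind(c(0.725, 1.0, 0.7875), c(-0.43, -0.546, -1))   # succeed / fail
  wts <- c(0.4, 0.35, 0.25)
  pv <- prospect_value(vt, c(0.75, 0.25), wts)
  combined <- as.numeric(vt %*% wts)
  expect_equal(pv, 0.65 * combined[1] + 0.35 * combined[2])
  # single certain outcome on a single criterion: PV equals the value itself
  expect_equal(prospect_value(matrix(0.42), 1, 1), 0.42)
  expect_error(prospect_value(vt, c(0.75, 0.25), c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("ranking is by descending value with input-order ties", {
  expect_equal(rank_alternatives(c(0.257, 0.431, 0.422)), c(2, 3, 1))
  expect_equal(rank_alternatives(c(0.470, 0.581, 0.594)), c(3, 2, 1))
  expect_equal(rank_alternatives(c(0.3, 0.3, 0.1)), c(1, 2, 3))
  expect_error(rank_alternatives(numeric(0)), "at least one")
})
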