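test_that("min-max normalization reproduces the printed panel", {
  norm <- normalize_panel(we$panel, we$criteria$type)
  # all twelve printed cells, criterion by criterion
  expect_printed(norm$lo[, 1], c(0.143, 0, 0.5, 0.714))
  expect_printed(norm$hi[, 1], c(0.714, 0.571, 0.857, 1.0))
  expect_printed(norm$lo[, 2], c(0.25, 0, 0.5, 0.25))
  expect_printed(norm$hi[, 2], c(0.875, 0.75, 1.0, 0.75))
  # criterion 3 was printed with an extra rounding pass (0.03/0.17 = 0.17647
  # appears as 0.177), so compare at one unit in the last printed digit
  expect_printed(norm$lo[, 3], c(0.177, 0, 0.294, 0.588), tol = 1e-3)
  expect_printed(norm$hi[, 3], c(0.765, 0.529, 0.882, 1.0), tol = 1e-3)
  expect_true(all(norm$lo >= 0 & norm$hi <= 1 & norm$lo <= norm$hi))
})

test_that("cost-type normalization reverses direction and keeps bounds ordered", {
  p <- expert_panel(lo = matrix(c(10, 20, 40)), hi = matrix(c(15, 30, 50)))
  ben <- normalize_panel(p, "benefit")
  cost <- normalize_panel(p, "cost")
  expect_true(all(cost$lo <= cost$hi))
  # reversal: the cost interval is the benefit interval reflected about [0, 1]
  expect_equal(cost$lo[, 1], 1 - ben$hi[, 1], ignore_attr = TRUE)
  expect_equal(cost$hi[, 1], 1 - ben$lo[, 1], ignore_attr = TRUE)
})

test_that("unanimous criterion normalizes to [0, 0] and contributes no distance", {
  p <- expert_panel(lo = cbind(c(5, 5, 5), c(1, 2, 3)),
                    hi = cbind(c(5, 5, 5), c(2, 3, 4)))
  norm <- normalize_panel(p)
  expect_true(all(norm$lo[, 1] == 0 & norm$hi[, 1] == 0))
  d <- distance_table(norm)
  expect_true(all(d$d[, 1] == 0))
})

test_that("mean reference matches the printed per-criterion means", {
  mr <- mean_reference(normalize_panel(we$panel, we$criteria$type))
  expect_printed(mr$lo, c(0.339, 0.25, 0.265))
  expect_printed(mr$hi, c(0.786, 0.844, 0.794))
  # single expert: the mean is that expert's own interval
  one <- expert_panel(lo = matrix(c(0.2, 0.4), 1), hi = matrix(c(0.3, 0.9), 1))
  expect_equal(mean_reference(one), list(lo = c(C1 = 0.2, C2 = 0.4),
                                         hi = c(C1 = 0.3, C2 = 0.9)))
})

test_that("distances to the mean reproduce the printed matrix", {
  norm <- normalize_panel(we$panel, we$criteria$type)
  d <- distance_table(norm)$d
  printed <- rbind(c(0.148, 0.022, 0.066),
                   c(0.284, 0.189, 0.265),
                   c(0.124, 0.209, 0.066),
                   c(0.305, 0.066, 0.271))
  # the published matrix was computed from the rounded normalized panel, so
  # full-precision distances can differ by up to one unit in the last digit
  expect_printed(d, printed, tol = 1e-3)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("an expert equal to the mean has zero distance and similarity K", {
  p <- expert_panel(lo = rbind(c(0.1, 0.2), c(0.1, 0.2)),
                    hi = rbind(c(0.5, 0.9), c(0.5, 0.9)))
  dt <- distance_table(p)
  expect_equal(unname(dt$d), matrix(0, 2, 2))
  expect_equal(dt$similarity, c(E1 = 2, E2 = 2))
})

test_that("similarity weights reproduce the printed expert weights", {
  norm <- normalize_panel(we$panel, we$criteria$type)
  w <- expert_weights(distance_table(norm))
  expect_printed(w, c(0.277, 0.227, 0.261, 0.236))
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("identical experts get equal weights and permutations commute", {
  set.seed(31)
  for (i in 1:20) {
    H <- sample(2:6, 1); K <- sample(1:4, 1)
    lo <- matrix(runif(K), H, K, byrow = TRUE)   # duplicated rows
    hi <- lo + matrix(runif(K), H, K, byrow = TRUE)
    w <- expert_weights(distance_table(normalize_panel(expert_panel(lo, hi))))
    expect_equal(unname(w), rep(1 / H, H))
    # distinct experts: permuting rows permutes weights
    lo2 <- matrix(runif(H * K), H, K); hi2 <- lo2 + matrix(runif(H * K), H, K)
    perm <- sample(H)
    w_a <- expert_weights(distance_table(normalize_panel(expert_panel(lo2, hi2))))
    w_b <- expert_weights(distance_table(normalize_panel(expert_panel(lo2[perm, , drop = FALSE],
                                                                      hi2[perm, , drop = FALSE]))))
    expect_equal(unname(w_b), unname(w_a)[perm])
  }
})

test_that("collective reference aggregates raw intervals on the original scale", {
  norm <- normalize_panel(we$panel, we$criteria$type)
  w <- expert_weights(distance_table(norm))
  r <- collective_reference(we$panel, w)
  expect_printed(r$lo, c(42.738, 50.068, 0.495))
  expect_printed(r$hi, c(49.012, 54.798, 0.586))
  # convexity: each bound within the hull of the experts' bounds
  expect_true(all(r$lo >= apply(we$panel$lo, 2, min) &
                  r$lo <= apply(we$panel$lo, 2, max)))
  expect_true(all(r$hi >= apply(we$panel$hi, 2, min) &
                  r$hi <= apply(we$panel$hi, 2, max)))
  # single expert with weight 1 recovers that expert's raw interval
  one <- expert_panel(lo = matrix(c(40, 50), 1, 2), hi = matrix(c(48, 55), 1, 2))
  expect_equal(collective_reference(one, 1), list(lo = c(40, 50), hi = c(48, 55)))
})

test_that("degenerate and invalid panels raise clear errors", {
  expect_error(expert_panel(lo = matrix(5), hi = matrix(4)), "malformed interval")
  expect_error(expert_panel(lo = matrix(numeric(0), 0, 0), hi = matrix(numeric(0), 0, 0)),
               "empty panel")
  # all distances equal to 1 leaves nothing to weight
  p <- expert_panel(lo = rbind(0, 1), hi = rbind(0, 1))
  dt <- distance_table(p, mean_ref = list(lo = 0.5, hi = 0.5))
  dt$similarity <- rep(0, 2)
  expect_error(expert_weights(dt), "total similarity is zero")
  expect_error(collective_reference(we$panel, c(0.5, 0.5)), "one weight per expert")
  expect_error(collective_reference(we$panel, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})
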