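#' The packaged surgical-emergency worked example
#'
#' A complete decision problem for an emergency surgery scenario: four
#' physicians give interval reference points on three benefit criteria
#' (immediate treatment effect, long-run post-surgery effect, ripple effect
#' on the hospital), and three response actions (traditional method,
#' standard treatment, new therapy) each succeed or fail with stated
#' probabilities, producing interval outcomes on every criterion. Criterion
#' weights are (0.4, 0.35, 0.25); CPT parameters are alpha = beta = 1,
#' lambda = 2, mu = 0.6. The same problem ships as a document at
#' \code{system.file("extdata", "worked_example.json", package = "cptgdm")}.
#'
#' @return A \code{\link{decision_problem}} with H = 4 experts, K = 3
#'   criteria, M = 3 alternatives and N = 2 outcomes.
#' @examples
#' solve_problem(worked_example())$prospect_values
#' @export
worked_example <- function() {
  criteria <- data.frame(
    name = c("C1", "C2", "C3"),
    type = "benefit",
    weight = c(0.4, 0.35, 0.25),
    stringsAsFactors = FALSE)
  panel <- expert_panel(
    lo = matrix(c(40, 38, 45, 48,   50, 48, 52, 50,   0.48, 0.45, 0.50, 0.55), 4, 3),
    hi = matrix(c(48, 46, 50, 52,   55, 54, 56, 54,   0.58, 0.54, 0.60, 0.62), 4, 3),
    experts = paste0("E", 1:4), criteria = criteria$name)
  # x[m, n, k]: outcome intervals, n = 1 succeed, n = 2 fail
  x_lo <- array(0, c(3, 2, 3)); x_hi <- array(0, c(3, 2, 3))
  x_lo[, 1, ] <- rbind(c(60, 80, 0.75), c(70, 72, 0.75), c(82, 75, 0.80))
  x_hi[, 1, ] <- rbind(c(70, 85, 0.80), c(75, 80, 0.85), c(88, 80, 0.84))
  x_lo[, 2, ] <- rbind(c(30, 40, 0.35), c(32, 46, 0.45), c(36, 35, 0.48))
  x_hi[, 2, ] <- rbind(c(40, 45, 0.40), c(42, 48, 0.50), c(44, 40, 0.50))
  decision_problem(
    criteria = criteria, panel = panel,
    alternatives = c("A1", "A2", "A3"),
    outcomes = c("succeed", "fail"),
    probs = rbind(c(0.75, 0.25), c(0.8, 0.2), c(0.7, 0.3)),
    x_lo = x_lo, x_hi = x_hi,
    params = cpt_params(alpha = 1, beta = 1, lambda = 2, mu = 0.6))
}

#' Generate a random well-formed decision problem
#'
#' Draws a seeded random problem satisfying every structural invariant, for
#' property-based testing and demonstration. Expert reference intervals and
#' outcome intervals are drawn per criterion from a configurable value
#' range; interval widths are uniform up to \code{max_width_frac} of that
#' range; outcome probabilities are sampled uniformly on the simplex
#' (normalized exponentials). Cost-type criteria are generated deliberately
#' (a \code{benefit_frac} below 1 guarantees the cost branch of the payoff
#' calculus is exercised); with K criteria, \code{round(K * benefit_frac)}
#' are benefit-type.
#'
#' @param seed integer seed; identical seed and shape give an identical
#'   problem (the seed is recorded in the document written by
#'   \code{\link{write_problem}} callers via its own field).
#' @param H,K,M,N numbers of experts, criteria, alternatives, outcomes.
#' @param benefit_frac fraction of benefit-type criteria in \code{[0, 1]}.
#' @param value_range length-2 range from which criterion scales are drawn.
#' @param max_width_frac maximum interval width as a fraction of the
#'   criterion range, in (0, 1].
#' @param params CPT parameters to embed.
#'
#' @return A \code{\link{decision_problem}}.
#' @examples
#' p <- generate_problem(seed = 1)
#' identical(p, generate_problem(seed = 1))
#' @export
generate_problem <- function(seed, H = 4, K = 3, M = 3, N = 2,
                             benefit_frac = 0.7,
                             value_range = c(0, 100),
                             max_width_frac = 0.2,
                             params = cpt_params()) {
  stopifnot(H >= 1, K >= 1, M >= 2, N >= 1)
  if (benefit_frac < 0 || benefit_frac > 1) {
    stop("benefit_frac must lie in [0, 1]", call. = FALSE)
  }
  rng <- diff(range(value_range))
  if (rng <= 0) stop("infeasible config: zero-width value range", call. = FALSE)
  if (max_width_frac <= 0 || max_width_frac > 1) {
    stop("max_width_frac must lie in (0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n_benefit <- round(K * benefit_frac)
  types <- c(rep("benefit", n_benefit), rep("cost", K - n_benefit))
  w <- stats::runif(K); w <- w / sum(w)
  criteria <- data.frame(name = paste0("C", seq_len(K)), type = types,
                         weight = w, stringsAsFactors = FALSE)

  draw_interval <- function(n) {
    lo <- min(value_range) + stats::runif(n) * rng * (1 - max_width_frac)
    wd <- stats::runif(n) * rng * max_width_frac
    list(lo = lo, hi = lo + wd)
  }
  ref <- draw_interval(H * K)
  panel <- expert_panel(matrix(ref$lo, H, K), matrix(ref$hi, H, K),
                        criteria = criteria$name)

  xv <- draw_interval(M * N * K)
  x_lo <- array(xv$lo, c(M, N, K)); x_hi <- array(xv$hi, c(M, N, K))

  probs <- matrix(stats::rexp(M * N), M, N)
  probs <- probs / rowSums(probs)
  if (N == 1L) probs[] <- 1

  decision_problem(criteria = criteria, panel = panel,
                   alternatives = paste0("A", seq_len(M)),
                   outcomes = paste0("outcome", seq_len(N)),
                   probs = probs, x_lo = x_lo, x_hi = x_hi, params = params)
}
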