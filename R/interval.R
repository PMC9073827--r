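#' Interval numbers
#'
#' An interval number \code{[lo, hi]} expresses an uncertain quantity by its
#' bounds. Intervals carry both attribute outcomes and reference points
#' throughout the package; a degenerate interval (\code{lo == hi}) is a crisp
#' value.
#'
#' @param lo numeric lower bound (scalar, finite).
#' @param hi numeric upper bound (scalar, finite), \code{hi >= lo}.
#'
#' @return A length-2 numeric vector of class \code{"interval"}.
#' @examples
#' interval(60, 70)
#' interval(0.5, 0.5) # crisp
#' @export
interval <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L || length(hi) != 1L ||
      !is.finite(lo) || !is.finite(hi)) {
    stop("interval bounds must be single finite numbers", call. = FALSE)
  }
  if (lo > hi) {
    stop(sprintf("malformed interval: lower bound %g exceeds upper bound %g", lo, hi),
         call. = FALSE)
  }
  structure(c(lo, hi), class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("[%g, %g]\n", x[1], x[2]))
  invisible(x)
}

# Coerce a length-2 numeric (or interval) to a validated interval.
as_interval <- function(x, what = "interval") {
  if (inherits(x, "interval")) return(x)
  if (!is.numeric(x) || length(x) != 2L) {
    stop(sprintf("%s must be a numeric [lo, hi] pair", what), call. = FALSE)
  }
  tryCatch(interval(x[1], x[2]),
           error = function(e) stop(sprintf("%s: %s", what, conditionMessage(e)),
                                    call. = FALSE))
}

#' Classify the relation between an attribute interval and a reference interval
#'
#' Two interval numbers can relate to each other in six qualitatively distinct
#' ways: the attribute interval \code{C} entirely below the reference \code{R}
#' (case 1), entirely above (case 2), overlapping from below (case 3),
#' overlapping from above (case 4), strictly containing \code{R} (case 5), or
#' nested inside \code{R} (case 6). Each case has its own gain/loss formula
#' (see \code{\link{interval_payoff}}).
#'
#' Boundary equalities are resolved by a fixed precedence (1, 2, 6, 5, 3, 4):
#' separation is tested first, then nesting of \code{C} in \code{R}, then
#' containment of \code{R} in \code{C}, then partial overlap. The precedence
#' guarantees exactly one case for every valid pair; identical intervals fall
#' in case 6 (zero payoff) and crisp inputs reduce to the usual sign
#' comparison.
#'
#' @param C attribute interval (an \code{\link{interval}} or \code{c(lo, hi)}).
#' @param R reference interval.
#'
#' @return Integer in \code{1:6}.
#' @examples
#' classify_relation(c(60, 70), c(42.738, 49.012)) # 2: C above R
#' classify_relation(c(36, 44), c(42.738, 49.012)) # 3: overlap from below
#' @export
classify_relation <- function(C, R) {
  C <- as_interval(C, "attribute interval C")
  R <- as_interval(R, "reference interval R")
  if (C[2] < R[1]) return(1L)
  if (C[1] > R[2]) return(2L)
  if (R[1] <= C[1] && C[2] <= R[2]) return(6L)
  if (C[1] <= R[1] && R[2] <= C[2]) return(5L)
  if (C[1] < R[1]) return(3L)
  4L
}

#' Gain/loss payoff of an interval outcome against an interval reference
#'
#' Converts an interval attribute value \code{C} into a crisp (gain, loss)
#' pair relative to the reference interval \code{R}, by the case-wise payoff
#' formulas for the six interval relations. For a benefit criterion, values
#' above the reference are gains; a cost criterion mirrors this (values below
#' the reference are gains), implemented as the negate-and-swap of the benefit
#' formulas so that gains are always nonnegative and losses nonpositive.
#'
#' Benefit-type formulas by case (midpoint \code{mid = 0.5 (C_lo + C_hi)}):
#' \describe{
#'   \item{1}{loss \code{mid - R_lo} (the uniform-density expectation of
#'     \code{x - R_lo} over \code{C}), gain 0}
#'   \item{2}{gain \code{mid - R_hi}, loss 0}
#'   \item{3}{loss \code{0.5 (C_lo - R_lo)}, gain 0}
#'   \item{4}{gain \code{0.5 (C_hi - R_hi)}, loss 0}
#'   \item{5}{gain \code{0.5 (C_hi - R_hi)} and loss \code{0.5 (C_lo - R_lo)}}
#'   \item{6}{both 0 (outcome inside the reference band)}
#' }
#' In case 5 both components are nonzero; they are kept separate so the value
#' function can treat them asymmetrically, and \code{net} is their sum for
#' reporting.
#'
#' @param C attribute interval.
#' @param R reference interval.
#' @param type \code{"benefit"} (larger is better) or \code{"cost"}.
#'
#' @return A list with components \code{gain} (>= 0), \code{loss} (<= 0),
#'   \code{net} (gain + loss) and \code{case} (the relation case used).
#' @examples
#' interval_payoff(c(60, 70), c(42.738, 49.012), "benefit") # gain 15.988
#' interval_payoff(c(30, 40), c(42.738, 49.012), "cost")    # gain  7.738
#' @export
interval_payoff <- function(C, R, type = c("benefit", "cost")) {
  type <- match.arg(type)
  C <- as_interval(C, "attribute interval C")
  R <- as_interval(R, "reference interval R")
  case <- classify_relation(C, R)
  mid <- 0.5 * (C[1] + C[2])
  gl <- switch(case,
    c(0, mid - R[1]),                                # 1: all below -> loss
    c(mid - R[2], 0),                                # 2: all above -> gain
    c(0, 0.5 * (C[1] - R[1])),                       # 3: low overlap -> loss
    c(0.5 * (C[2] - R[2]), 0),                       # 4: high overlap -> gain
    c(0.5 * (C[2] - R[2]), 0.5 * (C[1] - R[1])),     # 5: R inside C -> both
    c(0, 0)                                          # 6: C inside R -> none
  )
  if (type == "cost") gl <- c(-gl[2], -gl[1])  # mirror: gain <- -loss, loss <- -gain
  list(gain = gl[1], loss = gl[2], net = gl[1] + gl[2], case = case)
}

#' Expected payoff under a uniform density on the attribute interval
#'
#' Numerically integrates \code{(x - bound) f(x)} over \code{C}, where
#' \code{f} is the uniform density on \code{C} and the bound is \code{R_lo}
#' (case 1, outcome entirely below the reference) or \code{R_hi} (case 2,
#' entirely above). This is the probabilistic derivation behind the case-1/2
#' closed forms \code{0.5 (C_lo + C_hi) - bound}; it exists as an independent
#' numerical check of those formulas and applies only to cases 1 and 2, where
#' the whole interval sits on one side of the reference.
#'
#' @param C non-degenerate attribute interval (\code{lo < hi}, so the density
#'   exists).
#' @param R reference interval.
#'
#' @return The expected benefit-type payoff (a single number).
#' @export
uniform_expected_payoff <- function(C, R) {
  C <- as_interval(C, "attribute interval C")
  R <- as_interval(R, "reference interval R")
  if (C[1] >= C[2]) {
    stop("not applicable: degenerate attribute interval has no uniform density",
         call. = FALSE)
  }
  case <- classify_relation(C, R)
  if (!case %in% c(1L, 2L)) {
    stop("uniform expected payoff is defined only for separated intervals (cases 1-2)",
         call. = FALSE)
  }
  bound <- if (case == 1L) R[1] else R[2]
  dens <- 1 / (C[2] - C[1])
  stats::integrate(function(x) (x - bound) * dens, lower = C[1], upper = C[2],
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}
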