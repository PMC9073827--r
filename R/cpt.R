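#' Cumulative prospect theory parameters
#'
#' Bundles the behavioral parameters of the prospect-value calculation.
#' \code{alpha} and \code{beta} are the curvature exponents of the value
#' function for gains and losses (1 = linear, the reference setting);
#' \code{lambda >= 1} is the loss-aversion multiplier making losses loom
#' larger than equal-sized gains; \code{mu} is the slope of the neo-additive
#' probability weighting function (1 = no probability distortion).
#'
#' @param alpha gain curvature, in (0, 1].
#' @param beta loss curvature, in (0, 1].
#' @param lambda loss aversion, >= 1.
#' @param mu probability-weighting slope, in (0, 1].
#'
#' @return A list of class \code{"cpt_params"}.
#' @examples
#' cpt_params()               # alpha = beta = 1, lambda = 2, mu = 0.6
#' cpt_params(lambda = 1, mu = 1)  # risk-neutral in both senses
#' @export
cpt_params <- function(alpha = 1, beta = 1, lambda = 2, mu = 0.6) {
  chk <- function(x, nm, lo, hi, lo_open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (lo_open) x <= lo else x < lo) || x > hi) {
      stop(sprintf("%s must be a number in %s%g, %g]", nm,
                   if (lo_open) "(" else "[", lo, hi), call. = FALSE)
    }
  }
  chk(alpha, "alpha", 0, 1)
  chk(beta, "beta", 0, 1)
  chk(lambda, "lambda", 1, Inf, lo_open = FALSE)
  chk(mu, "mu", 0, 1)
  structure(list(alpha = alpha, beta = beta, lambda = lambda, mu = mu),
            class = "cpt_params")
}

#' @export
print.cpt_params <- function(x, ...) {
  cat(sprintf("CPT parameters: alpha = %g, beta = %g, lambda = %g, mu = %g\n",
              x$alpha, x$beta, x$lambda, x$mu))
  invisible(x)
}

#' Prospect-theory value function
#'
#' The piecewise power value function applied to each crisp payoff z:
#' \code{z^alpha} for gains (z >= 0) and \code{-lambda (-z)^beta} for losses.
#' Strictly increasing, zero at zero, and steeper for losses whenever
#' \code{lambda > 1}.
#'
#' @param z numeric vector of payoffs.
#' @param params a \code{\link{cpt_params}} object.
#' @return Numeric vector of subjective values, same length as \code{z}.
#' @examples
#' pt_value(c(15.988, -0.120), cpt_params())  # 15.988, -0.240
#' @export
pt_value <- function(z, params = cpt_params()) {
  stopifnot(inherits(params, "cpt_params"))
  ifelse(z >= 0, z^params$alpha, -params$lambda * (-z)^params$beta)
}

#' Neo-additive probability weighting function
#'
#' \code{w(p) = mu p + (1 - mu)/2} on the open interval (0, 1), with the
#' endpoints fixed at \code{w(0) = 0} and \code{w(1) = 1}. Small probabilities
#' are overweighted and large ones underweighted; at \code{mu = 1} the
#' function is the identity and decision weights reduce to the objective
#' probabilities. Satisfies \code{w(p) + w(1 - p) = 1} for every \code{mu}.
#'
#' @param p numeric vector of probabilities in \code{[0, 1]}.
#' @param mu slope parameter in (0, 1].
#' @return Numeric vector of distorted probabilities.
#' @examples
#' probability_weight(0.75, 0.6)  # 0.65
#' @export
probability_weight <- function(p, mu = 0.6) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p == 1, 1, ifelse(p == 0, 0, mu * p + 0.5 * (1 - mu)))
}

#' Rank-dependent decision weights for one prospect on one criterion
#'
#' Implements the cumulative (rank-dependent) weighting of CPT. Outcomes are
#' sorted by normalized value, best first (stable; ties and zero values stay
#' in input order, zeros ranked with the gains — their contribution is zero
#' either way). Gains, from the best downward, receive
#' \code{pi+_n = w(p_1 + ... + p_n) - w(p_1 + ... + p_(n-1))}; losses, from
#' the worst upward, receive
#' \code{pi-_n = w(p_n + ... + p_N) - w(p_(n+1) + ... + p_N)}. A single
#' weighting function serves both sides. For the neo-additive family the
#' weights telescope to \code{sum(pi+) + sum(pi-) = 1} for any outcome count.
#'
#' @param probabilities outcome probabilities (must sum to 1 within 1e-9).
#' @param values normalized values of the outcomes on this criterion (used
#'   only for ranking and gain/loss classification).
#' @param params a \code{\link{cpt_params}} (only \code{mu} is used).
#' @param identity_weighting if \code{TRUE}, use \code{w(p) = p} (objective
#'   probabilities) instead of the neo-additive function.
#'
#' @return Numeric vector of decision weights aligned with the INPUT outcome
#'   order; attribute \code{"is_gain"} flags which outcomes were ranked as
#'   gains.
#' @examples
#' decision_weights(c(0.75, 0.25), c(0.725, -0.613))  # 0.65, 0.35
#' @export
decision_weights <- function(probabilities, values, params = cpt_params(),
                             identity_weighting = FALSE) {
  stopifnot(inherits(params, "cpt_params"))
  N <- length(probabilities)
  if (length(values) != N) stop("need one value per outcome", call. = FALSE)
  if (abs(sum(probabilities) - 1) > 1e-9) {
    stop(sprintf("outcome probabilities sum to %.12g, not 1", sum(probabilities)),
         call. = FALSE)
  }
  w <- if (identity_weighting) identity else function(p) probability_weight(p, params$mu)
  ord <- order(-values, seq_len(N))          # best first, stable under ties
  v_s <- values[ord]
  p_s <- probabilities[ord]
  is_gain_s <- v_s >= 0
  m <- sum(is_gain_s)                        # gains occupy ranks 1..m
  # snap accumulated probabilities to the endpoints so w(1) = 1 / w(0) = 0
  # fire exactly despite floating-point summation (sums are validated to 1e-9)
  snap <- function(x) pmin(pmax(ifelse(abs(x - 1) <= 1e-9, 1, x), 0), 1)
  pi_s <- numeric(N)
  if (m > 0) {
    cum <- snap(cumsum(p_s[seq_len(m)]))
    pi_s[seq_len(m)] <- w(cum) - w(c(0, cum[-m]))
  }
  if (m < N) {
    idx <- (m + 1):N
    # decumulative sums from each loss rank down to the worst outcome
    tail_cum <- snap(rev(cumsum(rev(p_s[idx]))))
    pi_s[idx] <- w(tail_cum) - w(c(tail_cum[-1], 0))
  }
  pi <- numeric(N); pi[ord] <- pi_s
  is_gain <- logical(N); is_gain[ord] <- is_gain_s
  structure(pi, is_gain = is_gain)
}

#' Per-criterion normalization of valued payoffs
#'
#' Divides every subjective value on a criterion by that criterion's largest
#' absolute value \code{v*_k = max |v|} (taken after loss aversion), so that
#' criteria measured on wildly different scales can be aggregated with the
#' attribute weights. If a criterion's payoffs are all zero its normalized
#' values are all zero.
#'
#' @param v numeric array of subjective values with criteria on the LAST
#'   dimension (e.g. M x N x K), or a matrix with criteria in columns.
#' @return Array of the same shape with entries in \code{[-1, 1]};
#'   attribute \code{"v_star"} holds the per-criterion normalizers.
#' @export
normalize_values <- function(v) {
  dims <- dim(v)
  if (is.null(dims)) dims <- c(length(v), 1L)
  K <- dims[length(dims)]
  vm <- matrix(v, ncol = K)
  v_star <- apply(abs(vm), 2, max)
  scale <- ifelse(v_star > 0, 1 / v_star, 0)
  out <- sweep(vm, 2, scale, `*`)
  dim(out) <- dims
  dimnames(out) <- dimnames(v)
  structure(out, v_star = v_star)
}

#' Multi-attribute prospect value
#'
#' Aggregates one alternative's normalized values into its prospect value
#' \code{PV = sum_k w_k sum_n pi_nk v_nk}, where the decision weights
#' \code{pi_nk} are computed independently per criterion (an outcome may rank
#' as a gain on one criterion and a loss on another). With attribute weights
#' summing to 1 and values normalized, \code{|PV| <= 1}.
#'
#' @param vtilde N x K matrix of normalized values for one alternative
#'   (outcomes in rows, criteria in columns).
#' @param probabilities outcome probabilities (length N, sum 1).
#' @param criterion_weights attribute weights (length K, nonnegative, sum 1).
#' @param params \code{\link{cpt_params}}.
#' @param identity_weighting use objective probabilities instead of the
#'   neo-additive weighting.
#'
#' @return A single prospect value.
#' @export
prospect_value <- function(vtilde, probabilities, criterion_weights,
                           params = cpt_params(), identity_weighting = FALSE) {
  vtilde <- as.matrix(vtilde)
  K <- ncol(vtilde)
  if (length(criterion_weights) != K) stop("need one weight per criterion", call. = FALSE)
  if (any(criterion_weights < 0) || abs(sum(criterion_weights) - 1) > 1e-9) {
    stop("criterion weights must be nonnegative and sum to 1", call. = FALSE)
  }
  contrib <- vapply(seq_len(K), function(k) {
    pi_k <- decision_weights(probabilities, vtilde[, k], params, identity_weighting)
    sum(pi_k * vtilde[, k])
  }, numeric(1))
  sum(criterion_weights * contrib)
}

#' Rank alternatives by descending prospect value
#'
#' @param pv numeric vector of prospect values.
#' @return Integer permutation: \code{rank_alternatives(pv)[1]} is the index
#'   of the best alternative. Ties are broken by input order.
#' @examples
#' rank_alternatives(c(0.257, 0.431, 0.422))  # 2 3 1
#' @export
rank_alternatives <- function(pv) {
  if (length(pv) < 1L) stop("need at least one alternative", call. = FALSE)
  order(-pv, seq_along(pv))
}
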