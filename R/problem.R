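#' Construct and validate a group decision problem
#'
#' A decision problem bundles everything the pipeline needs: the criteria
#' (benefit/cost type and attribute weights), the expert panel of interval
#' reference points, the alternatives with their outcome probabilities and
#' interval attribute values, the CPT parameters, and solver options.
#'
#' @param criteria data frame with columns \code{name}, \code{type}
#'   (\code{"benefit"}/\code{"cost"}) and \code{weight} (nonnegative, summing
#'   to 1 within 1e-9).
#' @param panel an \code{\link{expert_panel}} with one column per criterion.
#' @param alternatives character vector of alternative names (M >= 2).
#' @param outcomes character vector of outcome names (length N >= 1).
#' @param probs M x N matrix of outcome probabilities; each row sums to 1
#'   within 1e-9.
#' @param x_lo,x_hi M x N x K arrays of interval attribute value bounds.
#' @param params a \code{\link{cpt_params}}.
#' @param options list; \code{probability_weighting} is
#'   \code{"neo_additive"} (default) or \code{"identity"}, and
#'   \code{expert_weights} is \code{"similarity"} (default) or an explicit
#'   numeric vector of length H.
#'
#' @return An object of class \code{"decision_problem"}.
#' @seealso \code{\link{load_problem}} to read one from a JSON/YAML document,
#'   \code{\link{worked_example}} for a complete packaged instance.
#' @export
decision_problem <- function(criteria, panel, alternatives, outcomes, probs,
                             x_lo, x_hi, params = cpt_params(),
                             options = list()) {
  criteria <- as.data.frame(criteria, stringsAsFactors = FALSE)
  need <- c("name", "type", "weight")
  if (!all(need %in% names(criteria))) {
    stop("criteria must have columns name, type, weight", call. = FALSE)
  }
  if (!all(criteria$type %in% c("benefit", "cost"))) {
    stop("criterion type must be 'benefit' or 'cost'", call. = FALSE)
  }
  if (any(criteria$weight < 0) || abs(sum(criteria$weight) - 1) > 1e-9) {
    stop(sprintf("criterion weights must be nonnegative and sum to 1 (got %.12g)",
                 sum(criteria$weight)), call. = FALSE)
  }
  stopifnot(inherits(panel, "expert_panel"), inherits(params, "cpt_params"))
  K <- nrow(criteria)
  if (ncol(panel$lo) != K) stop("panel has a different number of criteria", call. = FALSE)
  M <- length(alternatives); N <- length(outcomes)
  if (M < 2L) stop("need at least two alternatives", call. = FALSE)
  if (N < 1L) stop("need at least one outcome", call. = FALSE)
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(M, N))) stop("probs must be an M x N matrix", call. = FALSE)
  if (any(probs < 0) || any(probs > 1)) {
    stop("outcome probabilities must lie in [0, 1]", call. = FALSE)
  }
  bad <- which(abs(rowSums(probs) - 1) > 1e-9)
  if (length(bad) > 0L) {
    stop(sprintf("alternatives[%d]: outcome probabilities sum to %.12g, not 1",
                 bad[1], rowSums(probs)[bad[1]]), call. = FALSE)
  }
  for (a in list(x_lo, x_hi)) {
    if (!is.array(a) || length(dim(a)) != 3L || !all(dim(a) == c(M, N, K))) {
      stop("x_lo and x_hi must be M x N x K arrays", call. = FALSE)
    }
  }
  bad <- which(x_lo > x_hi, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("alternatives[%d].outcomes[%d].values[%d]: interval lower bound exceeds upper",
                 bad[1, 1], bad[1, 2], bad[1, 3]), call. = FALSE)
  }
  options <- validate_options(options, H = nrow(panel$lo))
  dimnames(probs) <- list(alternatives, outcomes)
  dimnames(x_lo) <- dimnames(x_hi) <- list(alternatives, outcomes, criteria$name)
  structure(list(criteria = criteria, panel = panel,
                 alternatives = alternatives, outcomes = outcomes,
                 probs = probs, x_lo = x_lo, x_hi = x_hi,
                 params = params, options = options),
            class = "decision_problem")
}

validate_options <- function(options, H) {
  defaults <- list(probability_weighting = "neo_additive",
                   expert_weights = "similarity")
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("options.%s: unknown option", unknown[1]), call. = FALSE)
  }
  options <- utils::modifyList(defaults, options)
  if (!options$probability_weighting %in% c("neo_additive", "identity")) {
    stop("options.probability_weighting must be 'neo_additive' or 'identity'",
         call. = FALSE)
  }
  ew <- options$expert_weights
  if (is.character(ew)) {
    if (!identical(ew, "similarity")) {
      stop("options.expert_weights must be 'similarity' or a numeric vector",
           call. = FALSE)
    }
  } else {
    ew <- as.numeric(ew)
    if (length(ew) != H || any(ew < 0) || abs(sum(ew) - 1) > 1e-9) {
      stop("options.expert_weights: explicit weights need one nonnegative entry per expert, summing to 1",
           call. = FALSE)
    }
    options$expert_weights <- ew
  }
  options
}

#' @export
print.decision_problem <- function(x, ...) {
  cat(sprintf("Decision problem: %d alternatives x %d outcomes x %d criteria, %d experts\n",
              length(x$alternatives), length(x$outcomes), nrow(x$criteria),
              nrow(x$panel$lo)))
  cat("Criteria:\n"); print(x$criteria, row.names = FALSE)
  print(x$params)
  invisible(x)
}
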