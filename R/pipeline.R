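#' Solve a group decision problem end-to-end
#'
#' Runs the five-stage procedure: (1) normalize the expert panel per
#' criterion; (2) derive similarity-based expert weights (or take the
#' explicit weights from \code{options$expert_weights}); (3) aggregate the
#' raw expert intervals into a collective interval reference point per
#' criterion; (4) convert every interval attribute value into a crisp
#' gain/loss payoff against the collective reference and apply the value
#' function and per-criterion normalization; (5) compute rank-dependent
#' decision weights and the prospect value of each alternative, then rank.
#'
#' All intermediates are retained in the returned report, so the payoff
#' table, normalized values and transition weights can be inspected
#' alongside the final ranking. The computation is deterministic: the same
#' problem always yields the same report.
#'
#' @param problem a \code{\link{decision_problem}}.
#' @return An object of class \code{"cpt_report"}: a list with
#'   \code{expert_weights}, \code{collective_reference}, \code{payoffs}
#'   (M x N x K net payoffs), \code{payoff_gain}/\code{payoff_loss},
#'   \code{values} (valued payoffs), \code{normalized_values}, \code{v_star},
#'   \code{transition_weights} (M x N x K decision weights),
#'   \code{prospect_values}, \code{ranking} (best first) and the problem
#'   itself.
#' @examples
#' rep <- solve_problem(worked_example())
#' rep$prospect_values        # 0.257 0.431 0.422 (to 3 d.p.)
#' rep$problem$alternatives[rep$ranking[1]]
#' @export
solve_problem <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  step <- "consensus"
  rep <- tryCatch({
    # -- consensus stage -------------------------------------------------
    ew <- problem$options$expert_weights
    if (is.character(ew)) {
      norm <- normalize_panel(problem$panel, problem$criteria$type)
      ew <- expert_weights(distance_table(norm))
    }
    ref <- collective_reference(problem$panel, ew)

    # -- payoff stage ----------------------------------------------------
    step <- "payoff"
    M <- length(problem$alternatives); N <- length(problem$outcomes)
    K <- nrow(problem$criteria)
    dn <- dimnames(problem$x_lo)
    gain <- loss <- rel <- array(0, dim = c(M, N, K), dimnames = dn)
    for (k in seq_len(K)) {
      R <- c(ref$lo[k], ref$hi[k])
      type <- problem$criteria$type[k]
      for (m in seq_len(M)) for (n in seq_len(N)) {
        p <- interval_payoff(c(problem$x_lo[m, n, k], problem$x_hi[m, n, k]), R, type)
        gain[m, n, k] <- p$gain; loss[m, n, k] <- p$loss; rel[m, n, k] <- p$case
      }
    }

    # -- valuation stage (gain and loss components valued separately) ----
    step <- "valuation"
    v <- pt_value(gain, problem$params) + pt_value(loss, problem$params)
    vt <- normalize_values(v)
    v_star <- attr(vt, "v_star")

    # -- prospect stage --------------------------------------------------
    step <- "prospect"
    idw <- problem$options$probability_weighting == "identity"
    tw <- array(0, dim = c(M, N, K), dimnames = dn)
    pv <- numeric(M)
    for (m in seq_len(M)) {
      for (k in seq_len(K)) {
        tw[m, , k] <- decision_weights(problem$probs[m, ], vt[m, , k],
                                       problem$params, identity_weighting = idw)
      }
      pv[m] <- prospect_value(matrix(vt[m, , ], nrow = N), problem$probs[m, ],
                              problem$criteria$weight, problem$params,
                              identity_weighting = idw)
    }
    names(pv) <- problem$alternatives

    list(expert_weights = stats::setNames(ew, problem$panel$experts),
         collective_reference = ref,
         relation_cases = rel,
         payoff_gain = gain, payoff_loss = loss, payoffs = gain + loss,
         values = v, normalized_values = strip_attr(vt), v_star = v_star,
         transition_weights = tw,
         prospect_values = pv,
         ranking = rank_alternatives(pv),
         problem = problem)
  }, error = function(e) {
    stop(sprintf("[%s stage] %s", step, conditionMessage(e)), call. = FALSE)
  })
  class(rep) <- "cpt_report"
  rep
}

strip_attr <- function(x) { attr(x, "v_star") <- NULL; x }

#' Re-solve a problem using a single criterion
#'
#' Puts the whole attribute weight on one criterion (weight 1 there, 0
#' elsewhere) and re-solves, isolating that criterion's influence on the
#' ranking.
#'
#' @param problem a \code{\link{decision_problem}}.
#' @param criterion index (1..K) or name of the criterion to keep.
#' @return A \code{"cpt_report"}.
#' @examples
#' single_criterion_run(worked_example(), "C1")$prospect_values
#' @export
single_criterion_run <- function(problem, criterion) {
  stopifnot(inherits(problem, "decision_problem"))
  K <- nrow(problem$criteria)
  if (is.character(criterion)) criterion <- match(criterion, problem$criteria$name)
  if (is.na(criterion) || criterion < 1 || criterion > K) {
    stop("unknown criterion", call. = FALSE)
  }
  problem$criteria$weight <- as.numeric(seq_len(K) == criterion)
  solve_problem(problem)
}

#' Re-solve a problem under alternative expert weight scenarios
#'
#' Bypasses the similarity-based weighting and injects each given expert
#' weight vector directly into the collective-reference aggregation, keeping
#' every other stage identical. Useful for sensitivity analysis: how much
#' does the chosen alternative depend on whose opinion counts?
#'
#' @param problem a \code{\link{decision_problem}}.
#' @param scenarios list of expert weight vectors (each nonnegative, summing
#'   to 1); names are carried into the result.
#' @return A list of \code{"cpt_report"} objects, one per scenario.
#' @examples
#' reps <- expert_weight_scenarios(worked_example(),
#'                                 list(only_E2 = c(0, 1, 0, 0)))
#' reps$only_E2$ranking[1]  # A1 wins when only expert 2 counts
#' @export
expert_weight_scenarios <- function(problem, scenarios) {
  stopifnot(inherits(problem, "decision_problem"), is.list(scenarios))
  lapply(scenarios, function(w) {
    problem$options$expert_weights <- w  # re-validated inside decision_problem paths
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9 || length(w) != nrow(problem$panel$lo)) {
      stop("scenario weights must be nonnegative, one per expert, and sum to 1",
           call. = FALSE)
    }
    solve_problem(problem)
  })
}

#' @export
print.cpt_report <- function(x, ...) {
  p <- x$problem
  cat("Group CPT decision report\n")
  cat(sprintf("  experts: %s\n", paste(sprintf("%s = %.3f", p$panel$experts,
                                               x$expert_weights), collapse = ", ")))
  cat("  collective reference points:\n")
  for (k in seq_len(nrow(p$criteria))) {
    cat(sprintf("    %-8s [%.3f, %.3f]\n", p$criteria$name[k],
                x$collective_reference$lo[k], x$collective_reference$hi[k]))
  }
  cat("  net payoffs (alternative x criterion, by outcome):\n")
  for (n in seq_along(p$outcomes)) {
    cat(sprintf("    outcome %s:\n", p$outcomes[n]))
    print(round(x$payoffs[, n, , drop = TRUE], 3))
  }
  cat("  prospect values and ranking:\n")
  for (i in x$ranking) {
    cat(sprintf("    %-8s PV = %.3f\n", p$alternatives[i], x$prospect_values[i]))
  }
  cat(sprintf("  best alternative: %s\n", p$alternatives[x$ranking[1]]))
  invisible(x)
}
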