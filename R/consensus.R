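#' Expert panel of interval reference points
#'
#' The consensus stage starts from an H x K matrix of interval reference
#' points: each of H experts states, for each of K criteria, the interval
#' value they regard as the boundary between gains and losses.
#'
#' @param lo,hi H x K numeric matrices of lower / upper bounds (\code{lo <= hi}
#'   cell-wise).
#' @param experts optional character vector of expert names (defaults to
#'   \code{E1..EH}).
#' @param criteria optional character vector of criterion names.
#'
#' @return An object of class \code{"expert_panel"}: a list with \code{lo},
#'   \code{hi}, \code{experts}, \code{criteria}.
#' @examples
#' expert_panel(lo = matrix(c(40, 38), 2, 1), hi = matrix(c(48, 46), 2, 1))
#' @export
expert_panel <- function(lo, hi, experts = NULL, criteria = NULL) {
  lo <- as.matrix(lo); hi <- as.matrix(hi)
  if (!all(dim(lo) == dim(hi))) stop("lo and hi must have identical dimensions", call. = FALSE)
  if (nrow(lo) < 1L || ncol(lo) < 1L) stop("empty panel: need at least one expert and one criterion", call. = FALSE)
  if (!all(is.finite(lo)) || !all(is.finite(hi))) stop("panel bounds must be finite", call. = FALSE)
  bad <- which(lo > hi, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("malformed interval at expert %d, criterion %d: lower bound exceeds upper",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  if (is.null(experts)) experts <- paste0("E", seq_len(nrow(lo)))
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(lo)))
  dimnames(lo) <- dimnames(hi) <- list(experts, criteria)
  structure(list(lo = lo, hi = hi, experts = experts, criteria = criteria),
            class = "expert_panel")
}

#' @export
print.expert_panel <- function(x, ...) {
  cat(sprintf("Expert panel: %d experts x %d criteria\n", nrow(x$lo), ncol(x$lo)))
  m <- matrix(sprintf("[%g, %g]", x$lo, x$hi), nrow(x$lo), dimnames = dimnames(x$lo))
  print(m, quote = FALSE)
  invisible(x)
}

#' Min-max normalization of an expert panel
#'
#' Rescales each criterion's reference intervals to the unit box so that
#' criteria measured on different scales become comparable for the distance
#' computation. Per criterion, the min and max are taken over all experts'
#' bounds (both lower and upper). Benefit criteria map \code{x} to
#' \code{(x - min) / (max - min)}; cost criteria reverse the direction,
#' mapping \code{x} to \code{(max - x) / (max - min)} with the resulting
#' bounds reordered so lower <= upper. A criterion on which all experts agree
#' exactly (zero range) is set to \code{[0, 0]} for every expert, so it
#' contributes no distance.
#'
#' @param panel an \code{\link{expert_panel}}.
#' @param criterion_types character vector of \code{"benefit"} / \code{"cost"},
#'   one per criterion (default: all benefit).
#'
#' @return An \code{expert_panel} whose bounds all lie in \code{[0, 1]}.
#' @export
normalize_panel <- function(panel, criterion_types = NULL) {
  stopifnot(inherits(panel, "expert_panel"))
  K <- ncol(panel$lo)
  if (is.null(criterion_types)) criterion_types <- rep("benefit", K)
  if (length(criterion_types) != K || !all(criterion_types %in% c("benefit", "cost"))) {
    stop("criterion_types must be 'benefit'/'cost', one per criterion", call. = FALSE)
  }
  lo <- panel$lo; hi <- panel$hi
  for (k in seq_len(K)) {
    mn <- min(lo[, k]); mx <- max(hi[, k])
    if (mx - mn <= 0) {           # degenerate: unanimous crisp agreement
      lo[, k] <- 0; hi[, k] <- 0
      next
    }
    rg <- mx - mn
    if (criterion_types[k] == "benefit") {
      a <- (panel$lo[, k] - mn) / rg
      b <- (panel$hi[, k] - mn) / rg
    } else {
      a <- (mx - panel$hi[, k]) / rg  # direction reversed; bounds swapped to keep lo <= hi
      b <- (mx - panel$lo[, k]) / rg
    }
    lo[, k] <- a; hi[, k] <- b
  }
  expert_panel(lo, hi, panel$experts, panel$criteria)
}

#' Mean normalized reference point per criterion
#'
#' The group's central opinion on each criterion: the arithmetic mean of the
#' normalized lower bounds and of the normalized upper bounds.
#'
#' @param norm a normalized \code{\link{expert_panel}}.
#' @return A list with \code{lo} and \code{hi}, numeric vectors of length K.
#' @export
mean_reference <- function(norm) {
  stopifnot(inherits(norm, "expert_panel"))
  list(lo = colMeans(norm$lo), hi = colMeans(norm$hi))
}

#' Interval distances to the mean and per-expert similarity
#'
#' Measures how far each expert's normalized reference interval sits from the
#' group mean on each criterion, using the root-mean-square of the two bound
#' differences:
#' \deqn{d_{hk} = \sqrt{((R^L_{hk} - \bar R^L_k)^2 + (R^H_{hk} - \bar R^H_k)^2)/2}.}
#' On normalized values each \code{d_hk} lies in \code{[0, 1]}. The similarity
#' score of expert h is \code{d_h = sum_k (1 - d_hk)}: experts whose opinions
#' track the group mean score higher.
#'
#' @param norm normalized \code{\link{expert_panel}}.
#' @param mean_ref output of \code{\link{mean_reference}} (computed from
#'   \code{norm} if omitted).
#'
#' @return A list with \code{d} (H x K distance matrix) and \code{similarity}
#'   (length-H vector of \code{d_h}).
#' @export
distance_table <- function(norm, mean_ref = NULL) {
  stopifnot(inherits(norm, "expert_panel"))
  if (is.null(mean_ref)) mean_ref <- mean_reference(norm)
  dlo <- sweep(norm$lo, 2, mean_ref$lo)
  dhi <- sweep(norm$hi, 2, mean_ref$hi)
  d <- sqrt((dlo^2 + dhi^2) / 2)
  list(d = d, similarity = rowSums(1 - d))
}

#' Similarity-based expert weights
#'
#' Normalizes the similarity scores into weights \code{w_h = d_h / sum_h d_h},
#' so the closer an expert's reference points are to the group mean, the more
#' that expert's raw intervals count in the collective reference.
#'
#' @param dist output of \code{\link{distance_table}}.
#' @return Numeric weight vector summing to 1.
#' @export
expert_weights <- function(dist) {
  s <- dist$similarity
  tot <- sum(s)
  if (!is.finite(tot) || tot <= 0) {
    stop("cannot weight experts: total similarity is zero (every distance equals 1)",
         call. = FALSE)
  }
  s / tot
}

#' Collective interval reference point per criterion
#'
#' Aggregates the experts' RAW reference intervals with the expert weights:
#' \code{r_k = sum_h w_h E_hk}, bound-wise, on the original measurement scale
#' of each criterion. The normalized panel is used only to derive the weights;
#' the collective reference must live on the raw scale because downstream
#' payoffs compare it against raw attribute values. Each bound is a convex
#' combination of the experts' corresponding bounds.
#'
#' @param panel the raw \code{\link{expert_panel}}.
#' @param weights expert weight vector (nonnegative, summing to 1).
#' @return A list with \code{lo} and \code{hi}, numeric length-K vectors.
#' @examples
#' \dontrun{
#' p <- worked_example()$panel
#' w <- expert_weights(distance_table(normalize_panel(p)))
#' collective_reference(p, w) # r_1 = [42.738, 49.012]
#' }
#' @export
collective_reference <- function(panel, weights) {
  stopifnot(inherits(panel, "expert_panel"))
  if (length(weights) != nrow(panel$lo)) {
    stop("need one weight per expert", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("expert weights must be nonnegative and sum to 1", call. = FALSE)
  }
  list(lo = as.numeric(crossprod(weights, panel$lo)),
       hi = as.numeric(crossprod(weights, panel$hi)))
}
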