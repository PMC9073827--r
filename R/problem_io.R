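#' Read a decision problem document
#'
#' Parses a JSON (canonical) or YAML problem document and validates it into a
#' \code{\link{decision_problem}}. The document mirrors the problem structure:
#' \preformatted{
#' {
#'   "criteria":     [{"name": "C1", "type": "benefit", "weight": 0.4}, ...],
#'   "experts":      [{"name": "E1", "reference_points": [[40,48], ...]}, ...],
#'   "alternatives": [{"name": "A1",
#'                     "outcomes": [{"name": "succeed", "probability": 0.75,
#'                                   "values": [[60,70], ...]}, ...]}, ...],
#'   "cpt":          {"alpha": 1, "beta": 1, "lambda": 2, "mu": 0.6},
#'   "options":      {"probability_weighting": "neo_additive",
#'                    "expert_weights": "similarity"}   // optional
#' }
#' }
#' Unknown fields are rejected, and every validation failure names the
#' offending document path (e.g. \code{alternatives[2].outcomes[1].probability}).
#'
#' @param path file path; dispatched on extension (\code{.json}, \code{.yaml},
#'   \code{.yml}).
#' @return A validated \code{\link{decision_problem}}.
#' @examples
#' p <- load_problem(system.file("extdata", "worked_example.json",
#'                               package = "cptgdm"))
#' solve_problem(p)$ranking
#' @export
load_problem <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported extension '.%s' (use .json, .yaml or .yml)", ext),
         call. = FALSE))
  problem_from_list(doc)
}

# Build a decision_problem from a parsed document, with path-qualified errors.
problem_from_list <- function(doc) {
  fail <- function(path, msg) stop(sprintf("%s: %s", path, msg), call. = FALSE)
  known <- c("criteria", "experts", "alternatives", "cpt", "options", "seed")
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0L) fail(unknown[1], "unknown field")
  for (f in c("criteria", "experts", "alternatives", "cpt")) {
    if (is.null(doc[[f]])) fail(f, "missing required field")
  }

  num1 <- function(x, path) {
    x <- unlist(x)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) fail(path, "must be a finite number")
    x
  }
  pair <- function(x, path) {
    x <- unlist(x)
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
      fail(path, "must be a numeric [lo, hi] pair")
    }
    if (x[1] > x[2]) fail(path, sprintf("interval lower bound %g exceeds upper bound %g", x[1], x[2]))
    x
  }
  obj <- function(x, path, fields) {
    if (!is.list(x)) fail(path, "must be an object")
    unknown <- setdiff(names(x), fields)
    if (length(unknown) > 0L) fail(paste0(path, ".", unknown[1]), "unknown field")
    x
  }

  crit <- doc$criteria
  K <- length(crit)
  if (K < 1L) fail("criteria", "need at least one criterion")
  criteria <- do.call(rbind, lapply(seq_len(K), function(k) {
    p <- sprintf("criteria[%d]", k)
    c0 <- obj(crit[[k]], p, c("name", "type", "weight"))
    ty <- as.character(c0$type %||% fail(paste0(p, ".type"), "missing"))
    if (!ty %in% c("benefit", "cost")) fail(paste0(p, ".type"), "must be 'benefit' or 'cost'")
    data.frame(name = as.character(c0$name %||% paste0("C", k)), type = ty,
               weight = num1(c0$weight, paste0(p, ".weight")),
               stringsAsFactors = FALSE)
  }))

  exps <- doc$experts
  H <- length(exps)
  if (H < 1L) fail("experts", "need at least one expert")
  lo <- hi <- matrix(NA_real_, H, K)
  enames <- character(H)
  for (h in seq_len(H)) {
    p <- sprintf("experts[%d]", h)
    e0 <- obj(exps[[h]], p, c("name", "reference_points"))
    enames[h] <- as.character(e0$name %||% paste0("E", h))
    rp <- e0$reference_points
    if (length(rp) != K) fail(paste0(p, ".reference_points"), sprintf("expected %d intervals, got %d", K, length(rp)))
    for (k in seq_len(K)) {
      iv <- pair(rp[[k]], sprintf("%s.reference_points[%d]", p, k))
      lo[h, k] <- iv[1]; hi[h, k] <- iv[2]
    }
  }

  alts <- doc$alternatives
  M <- length(alts)
  if (M < 2L) fail("alternatives", "need at least two alternatives")
  N <- length(obj(alts[[1]], "alternatives[1]", c("name", "outcomes"))$outcomes)
  if (N < 1L) fail("alternatives[1].outcomes", "need at least one outcome")
  anames <- character(M); onames <- NULL
  probs <- matrix(NA_real_, M, N)
  x_lo <- x_hi <- array(NA_real_, c(M, N, K))
  for (m in seq_len(M)) {
    p <- sprintf("alternatives[%d]", m)
    a0 <- obj(alts[[m]], p, c("name", "outcomes"))
    anames[m] <- as.character(a0$name %||% paste0("A", m))
    if (length(a0$outcomes) != N) fail(paste0(p, ".outcomes"), sprintf("expected %d outcomes, got %d", N, length(a0$outcomes)))
    for (n in seq_len(N)) {
      po <- sprintf("%s.outcomes[%d]", p, n)
      o0 <- obj(a0$outcomes[[n]], po, c("name", "probability", "values"))
      if (m == 1L) onames <- c(onames, as.character(o0$name %||% paste0("outcome", n)))
      probs[m, n] <- num1(o0$probability, paste0(po, ".probability"))
      if (length(o0$values) != K) fail(paste0(po, ".values"), sprintf("expected %d intervals, got %d", K, length(o0$values)))
      for (k in seq_len(K)) {
        iv <- pair(o0$values[[k]], sprintf("%s.values[%d]", po, k))
        x_lo[m, n, k] <- iv[1]; x_hi[m, n, k] <- iv[2]
      }
    }
    psum <- sum(probs[m, ])
    if (abs(psum - 1) > 1e-9) {
      fail(sprintf("%s.outcomes", p), sprintf("probabilities sum to %.12g, not 1", psum))
    }
  }

  cp <- obj(doc$cpt, "cpt", c("alpha", "beta", "lambda", "mu"))
  params <- tryCatch(
    cpt_params(alpha = num1(cp$alpha %||% 1, "cpt.alpha"),
               beta = num1(cp$beta %||% 1, "cpt.beta"),
               lambda = num1(cp$lambda %||% 2, "cpt.lambda"),
               mu = num1(cp$mu %||% 0.6, "cpt.mu")),
    error = function(e) fail("cpt", conditionMessage(e)))

  options <- doc$options %||% list()
  if (length(options) > 0L) {
    obj(options, "options", c("probability_weighting", "expert_weights"))
    if (!is.null(options$expert_weights) && !is.character(options$expert_weights)) {
      options$expert_weights <- unlist(options$expert_weights)
    }
  }

  decision_problem(criteria = criteria,
                   panel = expert_panel(lo, hi, enames, criteria$name),
                   alternatives = anames, outcomes = onames,
                   probs = probs, x_lo = x_lo, x_hi = x_hi,
                   params = params, options = options)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialize a decision_problem back to the document structure.
problem_to_list <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  K <- nrow(problem$criteria)
  list(
    criteria = lapply(seq_len(K), function(k) {
      list(name = problem$criteria$name[k], type = problem$criteria$type[k],
           weight = problem$criteria$weight[k])
    }),
    experts = lapply(seq_along(problem$panel$experts), function(h) {
      list(name = problem$panel$experts[h],
           reference_points = lapply(seq_len(K), function(k)
             c(problem$panel$lo[h, k], problem$panel$hi[h, k])))
    }),
    alternatives = lapply(seq_along(problem$alternatives), function(m) {
      list(name = problem$alternatives[m],
           outcomes = lapply(seq_along(problem$outcomes), function(n) {
             list(name = problem$outcomes[n],
                  probability = problem$probs[m, n],
                  values = lapply(seq_len(K), function(k)
                    c(problem$x_lo[m, n, k], problem$x_hi[m, n, k])))
           }))
    }),
    cpt = unclass(problem$params),
    options = problem$options
  )
}

#' Write a decision problem document
#'
#' Serializes a \code{\link{decision_problem}} to JSON (or YAML, by
#' extension) in the same schema accepted by \code{\link{load_problem}};
#' numbers are written at full double precision so load/write round-trips
#' are lossless.
#'
#' @param problem a \code{\link{decision_problem}}.
#' @param path output path ending in \code{.json}, \code{.yaml} or \code{.yml}.
#' @return \code{path}, invisibly.
#' @export
write_problem <- function(problem, path) {
  doc <- problem_to_list(problem)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(doc, path),
    stop(sprintf("unsupported extension '.%s'", ext), call. = FALSE))
  invisible(path)
}

#' Write a solved report
#'
#' \code{format = "json"} writes every intermediate (expert weights,
#' collective reference, payoff table, normalized values, transition weights,
#' prospect values, ranking) machine-readably at full precision, together
#' with the CPT parameters used. \code{format = "text"} writes the
#' human-readable tables printed by \code{print.cpt_report}.
#'
#' @param report a \code{"cpt_report"} from \code{\link{solve_problem}}.
#' @param path output file path.
#' @param format \code{"json"} or \code{"text"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "cpt_report"))
  if (format == "text") {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
    return(invisible(path))
  }
  p <- report$problem
  out <- list(
    parameters = unclass(p$params),
    options = p$options,
    expert_weights = as.list(report$expert_weights),
    collective_reference = stats::setNames(
      lapply(seq_along(report$collective_reference$lo), function(k)
        c(report$collective_reference$lo[k], report$collective_reference$hi[k])),
      p$criteria$name),
    payoffs = array_to_list(report$payoffs),
    normalized_values = array_to_list(report$normalized_values),
    transition_weights = array_to_list(report$transition_weights),
    v_star = stats::setNames(as.list(report$v_star), p$criteria$name),
    prospect_values = as.list(report$prospect_values),
    ranking = p$alternatives[report$ranking]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# M x N x K array -> nested named lists (alternative -> outcome -> criteria vector)
array_to_list <- function(a) {
  dn <- dimnames(a)
  stats::setNames(lapply(seq_len(dim(a)[1]), function(m) {
    stats::setNames(lapply(seq_len(dim(a)[2]), function(n) {
      stats::setNames(as.list(a[m, n, ]), dn[[3]])
    }), dn[[2]])
  }), dn[[1]])
}
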