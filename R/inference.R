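#' Error condition for impossible evidence
#' @noRd
.impossible_evidence <- function(evidence) {
  stop(structure(
    class = c("bn_impossible_evidence", "error", "condition"),
    list(message = paste0(
      "evidence has probability zero under the model: ",
      paste(names(evidence), unlist(evidence), sep = " = ", collapse = ", ")),
      call = NULL)))
}

.check_evidence <- function(structure, evidence) {
  if (is.null(evidence) || !length(evidence)) return(list())
  evidence <- as.list(evidence)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named list/vector of states", call. = FALSE)
  for (v in names(evidence)) {
    var <- structure$variables[[v]]
    if (is.null(var)) stop("unknown evidence variable '", v, "'", call. = FALSE)
    if (!(evidence[[v]] %in% var$states))
      stop("illegal state '", evidence[[v]], "' for '", v, "'", call. = FALSE)
  }
  evidence
}

#' Exact joint marginal by variable elimination
#'
#' Computes `P(vars | evidence)` exactly by sum-product variable
#' elimination.  The default elimination order is min-fill with a
#' deterministic tie-break by canonical variable order; any order over the
#' eliminated variables gives the same result.
#'
#' @param model An `hfacs_bn` model.
#' @param vars Character vector of query variables (kept in the result).
#' @param evidence Named list/vector `variable = state`; may be empty.
#' @param elimination_order Optional permutation of the eliminated
#'   variables.
#' @return A named numeric array over the query variables (dimnames = state
#'   labels), normalized to sum to 1.
#' @export
bn_marginal <- function(model, vars, evidence = NULL, elimination_order = NULL) {
  model <- .as_model(model)
  structure <- model$structure
  nm <- names(structure$variables)
  if (!all(vars %in% nm)) stop("unknown query variable(s)", call. = FALSE)
  evidence <- .check_evidence(structure, evidence)
  overlap <- intersect(vars, names(evidence))
  if (length(overlap))
    stop("query variable(s) present in evidence: ",
         paste(overlap, collapse = ", "), call. = FALSE)

  factors <- lapply(nm, .f_from_cpt, structure = structure, cpts = model$cpts)
  for (v in names(evidence)) {
    k <- match(evidence[[v]], structure$variables[[v]]$states)
    factors <- lapply(factors, .f_reduce, var = v, state_idx = k)
  }
  elim <- setdiff(nm, c(vars, names(evidence)))
  if (is.null(elimination_order)) {
    elimination_order <- .min_fill_order(lapply(factors, `[[`, "vars"), elim, nm)
  } else {
    if (!setequal(elimination_order, elim))
      stop("'elimination_order' must be a permutation of the eliminated variables",
           call. = FALSE)
  }
  for (v in elimination_order) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    f <- Reduce(.f_product, factors[touch])
    factors <- c(factors[!touch], list(.f_sumout(f, v)))
  }
  res <- Reduce(.f_product, factors)
  z <- sum(res$val)
  if (!is.finite(z) || z <= 0) .impossible_evidence(evidence)
  res$val <- res$val / z
  res <- .f_permute(res, vars)
  out <- array(res$val, dim = res$card,
               dimnames = lapply(vars, function(v) structure$variables[[v]]$states))
  names(dimnames(out)) <- vars
  out
}

#' Posterior distribution of one variable
#'
#' Belief updating by Bayes' rule: the conditional distribution of `query`
#' given the evidence, computed exactly by variable elimination.
#'
#' @inheritParams bn_marginal
#' @param query Single variable name; must not appear in the evidence.
#' @return Object of class `bn_posterior`: a named probability vector with
#'   attributes `variable` and `evidence`.
#' @seealso [enumerate_posterior()] for the brute-force oracle.
#' @export
bn_posterior <- function(model, query, evidence = NULL, elimination_order = NULL) {
  .assert_scalar_chr(query, "query")
  m <- bn_marginal(model, query, evidence, elimination_order)
  out <- as.numeric(m)
  names(out) <- dimnames(m)[[1L]]
  structure(out, variable = query, evidence = evidence, class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, digits = 4, ...) {
  ev <- attr(x, "evidence")
  cat("Posterior of", attr(x, "variable"))
  if (length(ev))
    cat(" |", paste(names(ev), unlist(ev), sep = " = ", collapse = ", "))
  cat("\n")
  print(round(unclass(x)[seq_along(x)], digits))
  invisible(x)
}

#' Posterior by full-joint enumeration (oracle)
#'
#' Brute-force reference implementation: enumerates every full assignment of
#' the network (236,196 for the 12-variable HFACS model), scores each by the
#' chain-rule product of CPT entries, and sums the cells consistent with the
#' evidence.  Deliberately independent of the variable-elimination code
#' path; used as the correctness oracle in the test suite.
#'
#' @inheritParams bn_posterior
#' @return A `bn_posterior`.
#' @export
enumerate_posterior <- function(model, query, evidence = NULL) {
  model <- .as_model(model)
  structure <- model$structure
  nm <- names(structure$variables)
  .assert_scalar_chr(query, "query")
  if (!query %in% nm) stop("unknown query variable", call. = FALSE)
  evidence <- .check_evidence(structure, evidence)
  if (query %in% names(evidence))
    stop("query variable present in evidence", call. = FALSE)

  card <- .cards(structure)
  grid <- as.matrix(expand.grid(lapply(card, seq_len), KEEP.OUT.ATTRS = FALSE))
  w <- rep(1, nrow(grid))
  for (v in nm) {
    pa <- structure$parents[[v]]
    conf <- if (length(pa)) .mixed_radix(grid[, pa, drop = FALSE],
                                         card[pa]) else rep(1L, nrow(grid))
    nc <- .n_parent_configs(structure, v)
    w <- w * as.vector(model$cpts[[v]])[(grid[, v] - 1L) * nc + conf]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence))
    keep <- keep & grid[, v] == match(evidence[[v]], structure$variables[[v]]$states)
  states <- structure$variables[[query]]$states
  p <- vapply(seq_along(states), function(k)
    sum(w[keep & grid[, query] == k]), numeric(1))
  z <- sum(p)
  if (!is.finite(z) || z <= 0) .impossible_evidence(evidence)
  structure(stats::setNames(p / z, states), variable = query,
            evidence = evidence, class = "bn_posterior")
}

#' Predict the NSI posterior for one (possibly partial) case
#'
#' Conditions the network on every non-missing predictor value of a record
#' and returns the posterior of the outcome; missing predictors are simply
#' marginalized out.
#'
#' @param model An `hfacs_bn` model.
#' @param record Named character vector / one-row data frame of predictor
#'   states; `NA` entries are ignored.  Must not contain the outcome.
#' @param outcome Outcome variable name (default `"nsi"`).
#' @return A `bn_posterior` over the outcome states.
#' @export
predict_case <- function(model, record, outcome = "nsi") {
  model <- .as_model(model)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- unlist(lapply(record, as.character))
  }
  record <- record[!is.na(record)]
  if (outcome %in% names(record))
    stop("record must not contain the outcome '", outcome, "'", call. = FALSE)
  known <- intersect(names(model$structure$variables), names(record))
  ev <- as.list(record[known])
  bn_posterior(model, outcome, if (length(ev)) ev else NULL)
}
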