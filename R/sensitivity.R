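#' Mutual information between a predictor and the outcome
#'
#' `MI = sum_{x,y} P(x, y) log2[ P(x, y) / (P(x) P(y)) ]` in bits, with the
#' pairwise joint obtained by exact inference; also reported as a percent
#' of the outcome entropy, `100 * MI / H(outcome)` -- the share of outcome
#' uncertainty removed by observing the predictor.
#'
#' @param model An `hfacs_bn` model.
#' @param predictor Predictor variable name.
#' @param outcome Outcome variable name (default `"nsi"`).
#' @return List with `bits`, `percent` and `outcome_entropy` (bits).
#' @export
mutual_information <- function(model, predictor, outcome = "nsi") {
  if (identical(predictor, outcome))
    stop("predictor and outcome must differ", call. = FALSE)
  j <- bn_marginal(model, c(predictor, outcome))
  px <- rowSums(j); py <- colSums(j)
  nz <- j > 0
  mi <- sum(j[nz] * log2(j[nz] / outer(px, py)[nz]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  list(bits = max(0, mi), percent = if (hy > 0) 100 * max(0, mi) / hy else 0,
       outcome_entropy = hy)
}

#' Best and worst predictor states by predictive reasoning
#'
#' Conditions the network on each state of the predictor in turn and reads
#' off the posterior percentage of the favourable outcome state
#' (`"NSIs = no"`).  The worst state gives the minimum posterior, the best
#' the maximum; ties resolve to the earliest state in state order.
#'
#' @inheritParams mutual_information
#' @param favourable Favourable outcome state (default `"no"`).
#' @return List with `worst_state`, `worst_pct`, `best_state`, `best_pct`
#'   and the per-state vector `posterior_pct`.
#' @export
best_worst_scan <- function(model, predictor, outcome = "nsi",
                            favourable = "no") {
  model <- .as_model(model)
  if (identical(predictor, outcome))
    stop("predictor and outcome must differ", call. = FALSE)
  states <- model$structure$variables[[predictor]]$states
  post <- vapply(states, function(s) {
    100 * bn_posterior(model, outcome,
                       stats::setNames(list(s), predictor))[[favourable]]
  }, numeric(1))
  list(worst_state = states[which.min(post)], worst_pct = min(post),
       best_state = states[which.max(post)], best_pct = max(post),
       posterior_pct = post)
}

#' Sensitivity index from worst/best posteriors
#'
#' Relative percent increase of the favourable-outcome posterior when a
#' predictor moves from its worst to its best state:
#' `100 * (best - worst) / worst`.  This is the summary the package's
#' sensitivity report ranks predictors by (see
#' [nsi_reference_sensitivity()] for the published benchmark rows it
#' reproduces).
#'
#' @param worst_pct,best_pct Posterior percentages of the favourable state
#'   under the predictor's worst and best states.
#' @return Sensitivity index in percent.
#' @examples
#' sensitivity_index(62.8, 79.5)   # 26.6 (to one decimal)
#' @export
sensitivity_index <- function(worst_pct, best_pct) {
  if (any(worst_pct <= 0))
    stop("sensitivity index undefined for a zero worst-state posterior",
         call. = FALSE)
  100 * (best_pct - worst_pct) / worst_pct
}

.level_group <- function(level) {
  switch(as.character(level),
         "2" = "Preconditions for unsafe acts",
         "3" = "Unsafe supervision",
         "4" = "Organizational influences",
         paste("Level", level))
}

#' Rank predictors by sensitivity and mutual information
#'
#' Builds the full sensitivity report: for every predictor, the worst and
#' best states with their favourable-outcome posteriors, the sensitivity
#' index, and the mutual information with the outcome (bits and percent of
#' outcome entropy).  Rows are grouped by HFACS level (preconditions,
#' unsafe supervision, organizational influences) and sorted within each
#' group by decreasing sensitivity index.
#'
#' @param model An `hfacs_bn` model over the HFACS catalog.
#' @param outcome Outcome variable name (default `"nsi"`).
#' @param favourable Favourable outcome state (default `"no"`).
#' @return Object of class `nsi_sensitivity`: a data frame with columns
#'   `predictor`, `group`, `level`, `worst_state`, `worst_pct`,
#'   `best_state`, `best_pct`, `sensitivity_pct`, `mi_bits`, `mi_pct`.
#' @export
sensitivity_analysis <- function(model, outcome = "nsi", favourable = "no") {
  model <- .as_model(model)
  vars <- model$structure$variables
  predictors <- setdiff(names(vars), outcome)
  rows <- lapply(predictors, function(p) {
    bw <- best_worst_scan(model, p, outcome, favourable)
    mi <- mutual_information(model, p, outcome)
    data.frame(predictor = p, level = vars[[p]]$level,
               group = .level_group(vars[[p]]$level),
               worst_state = bw$worst_state, worst_pct = bw$worst_pct,
               best_state = bw$best_state, best_pct = bw$best_pct,
               sensitivity_pct = sensitivity_index(bw$worst_pct, bw$best_pct),
               mi_bits = mi$bits, mi_pct = mi$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$level, -out$sensitivity_pct), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nsi_sensitivity", "data.frame")
  out
}

#' @export
print.nsi_sensitivity <- function(x, ...) {
  cat("Sensitivity of the outcome to each predictor\n")
  cat(sprintf("  %-22s %-12s %-12s %11s %16s\n", "", "Worst state",
              "Best state", "Sensitivity", "Mutual info"))
  for (g in unique(x$group)) {
    cat(g, "\n")
    for (i in which(x$group == g))
      cat(sprintf("  %-22s %-4s %6.1f  %-4s %6.1f  %10.1f  %10.3f (%.1f)\n",
                  x$predictor[i],
                  substr(x$worst_state[i], 1, 4), x$worst_pct[i],
                  substr(x$best_state[i], 1, 4), x$best_pct[i],
                  x$sensitivity_pct[i], x$mi_bits[i], x$mi_pct[i]))
  }
  invisible(x)
}

#' Evaluate an intervention strategy
#'
#' Predictive reasoning on a what-if scenario: the network is conditioned
#' on the evidence set (for a simple strategy, one variable forced to its
#' best state; for a joint strategy, several), and the resulting posterior
#' of the favourable outcome state is compared with the no-evidence
#' baseline.  The complement of the favourable posterior is reported as
#' the predicted NSI rate under the intervention.
#'
#' By default the intervention is ordinary observational conditioning.
#' `mode = "do"` instead applies do-style graph surgery (each evidence
#' node's CPT is replaced by a point mass, severing its dependence on its
#' parents) for comparison.
#'
#' @param model An `hfacs_bn` model.
#' @param evidence Named list/vector `variable = state`; must not contain
#'   the outcome.  Empty evidence returns the baseline.
#' @param outcome Outcome variable name (default `"nsi"`).
#' @param favourable Favourable outcome state (default `"no"`).
#' @param mode `"evidence"` (conditioning, default) or `"do"` (graph
#'   surgery).
#' @return Object of class `nsi_intervention`: list with `evidence`,
#'   `favourable_pct` (posterior percent of the favourable state),
#'   `nsi_rate_pct` (its complement), `baseline_pct`,
#'   `baseline_rate_pct`, `change_pp` (percentage-point change in the
#'   favourable posterior) and `mode`.
#' @examples
#' truth <- make_ground_truth(generator_config(seed = 1))
#' evaluate_intervention(truth, list(safety_motivation = "good"))
#' @export
evaluate_intervention <- function(model, evidence = NULL, outcome = "nsi",
                                  favourable = "no",
                                  mode = c("evidence", "do")) {
  model <- .as_model(model)
  mode <- match.arg(mode)
  evidence <- .check_evidence(model$structure, evidence)
  if (outcome %in% names(evidence))
    stop("evidence must not contain the outcome", call. = FALSE)
  baseline <- 100 * bn_posterior(model, outcome)[[favourable]]
  if (!length(evidence)) {
    post <- baseline
  } else if (mode == "evidence") {
    post <- 100 * bn_posterior(model, outcome, evidence)[[favourable]]
  } else {
    surg <- model
    for (v in names(evidence)) {
      k <- match(evidence[[v]], model$structure$variables[[v]]$states)
      m <- model$cpts[[v]]
      m[] <- 0; m[, k] <- 1
      surg$cpts[[v]] <- m
    }
    post <- 100 * bn_posterior(surg, outcome)[[favourable]]
  }
  structure(list(evidence = evidence, favourable_pct = post,
                 nsi_rate_pct = 100 - post, baseline_pct = baseline,
                 baseline_rate_pct = 100 - baseline,
                 change_pp = post - baseline, mode = mode),
            class = "nsi_intervention")
}

#' @export
print.nsi_intervention <- function(x, ...) {
  cat("Intervention (", x$mode, " mode)\n", sep = "")
  if (length(x$evidence))
    cat("  evidence:", paste(names(x$evidence), unlist(x$evidence),
                             sep = " = ", collapse = ", "), "\n")
  else cat("  evidence: none (baseline)\n")
  cat(sprintf("  P(favourable outcome): %.1f%% (baseline %.1f%%, change %+.1f pp)\n",
              x$favourable_pct, x$baseline_pct, x$change_pp))
  cat(sprintf("  predicted NSI rate:    %.1f%%\n", x$nsi_rate_pct))
  invisible(x)
}
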