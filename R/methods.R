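#' @export
print.hfacs_bn <- function(x, ...) {
  cat("HFACS Bayesian network (", length(x$structure$variables), " nodes, ",
      sum(vapply(x$structure$parents, length, 0L)), " edges, ",
      bn_parameter_count(x$structure), " CPT entries)\n", sep = "")
  if (!is.null(x$loglik))
    cat(sprintf("  fitted by EM on %d records: log-likelihood %.2f after %d iteration(s)%s\n",
                x$n, x$loglik, x$iterations,
                if (isTRUE(x$converged)) "" else " (not converged)"))
  if (!is.null(x$generator))
    cat("  synthetic ground truth calibrated to target marginals\n")
  invisible(x)
}

#' @export
summary.hfacs_bn <- function(object, ...) {
  marg <- lapply(names(object$structure$variables), function(v)
    bn_posterior(object, v))
  names(marg) <- names(object$structure$variables)
  out <- list(model = object, marginals = marg)
  class(out) <- "summary.hfacs_bn"
  out
}

#' @export
print.summary.hfacs_bn <- function(x, digits = 3, ...) {
  print(x$model)
  cat("\nExact marginal distributions:\n")
  for (v in names(x$marginals)) {
    p <- x$marginals[[v]]
    cat(sprintf("  %-22s %s\n", v,
                paste(sprintf("%s %.1f%%", names(p)[seq_along(p)],
                              100 * as.numeric(p)), collapse = "  ")))
  }
  invisible(x)
}

#' Extract conditional probability tables
#'
#' @param object An `hfacs_bn` model.
#' @param node Optional node name; default returns the full list.
#' @param ... Unused.
#' @return A CPT matrix (rows = canonical parent configurations) or the
#'   named list of all of them.
#' @export
coef.hfacs_bn <- function(object, node = NULL, ...) {
  if (is.null(node)) return(object$cpts)
  object$cpts[[node]] %||% stop("unknown node '", node, "'", call. = FALSE)
}

#' @export
logLik.hfacs_bn <- function(object, ...) {
  if (is.null(object$loglik))
    stop("model was not fitted to data; use bn_loglik()", call. = FALSE)
  structure(object$loglik, df = bn_parameter_count(object$structure) -
              sum(vapply(names(object$structure$variables), function(v)
                .n_parent_configs(object$structure, v), integer(1))),
            nobs = object$n, class = "logLik")
}

#' Predict outcome posteriors for new cases
#'
#' @param object An `hfacs_bn` model.
#' @param newdata Data frame of discretized predictor states (`NA`
#'   allowed; an outcome column, if present, is ignored).
#' @param outcome Outcome variable (default `"nsi"`).
#' @param type `"prob"` for the posterior matrix, `"state"` for the
#'   argmax label (ties to the first state in state order).
#' @param ... Unused.
#' @return Matrix of posterior probabilities (cases x outcome states) or a
#'   character vector of predicted states.
#' @export
predict.hfacs_bn <- function(object, newdata, outcome = "nsi",
                             type = c("prob", "state"), ...) {
  type <- match.arg(type)
  predictors <- setdiff(colnames(newdata), outcome)
  states <- object$structure$variables[[outcome]]$states
  pred <- t(vapply(seq_len(nrow(newdata)), function(i)
    as.numeric(predict_case(object, newdata[i, predictors, drop = FALSE],
                            outcome)),
    numeric(length(states))))
  colnames(pred) <- states
  if (type == "prob") return(pred)
  states[apply(pred, 1L, which.max)]
}

#' Simulate latent cases from the model
#'
#' Ancestral sampling of full 12-variable state assignments from the joint
#' distribution.
#'
#' @param object An `hfacs_bn` model.
#' @param nsim Number of cases.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of state labels, `nsim` rows.
#' @export
simulate.hfacs_bn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  .labels_from_states(object$structure, .ancestral_sample(object, nsim))
}

#' Plot the layered network
#'
#' Draws the directed acyclic graph with one row per HFACS level
#' (organizational influences at the top, the outcome at the bottom) using
#' base graphics.
#'
#' @param x An `hfacs_bn` model or a `bn_structure`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hfacs_bn <- function(x, ...) {
  plot(x$structure, ...)
  invisible(x)
}

#' @export
plot.bn_structure <- function(x, ...) {
  lv <- vapply(x$variables, `[[`, integer(1), "level")
  if (anyNA(lv)) lv <- rep(1L, length(x$variables))
  nm <- names(x$variables)
  ys <- (lv - min(lv)) / max(1, diff(range(lv)))
  xs <- stats::ave(seq_along(nm), lv, FUN = function(i)
    if (length(i) == 1L) 0.5 else seq(0.08, 0.92, length.out = length(i)))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(-0.08, 1.1), axes = FALSE,
                 xlab = "", ylab = "", ...)
  e <- bn_edges(x)
  for (i in seq_len(nrow(e))) {
    a <- match(e$from[i], nm); b <- match(e$to[i], nm)
    graphics::arrows(xs[a], ys[a] - 0.03, xs[b], ys[b] + 0.05,
                     length = 0.07, col = "grey60")
  }
  graphics::points(xs, ys, pch = 21, bg = "white", cex = 3)
  graphics::text(xs, ys + 0.055, gsub("_", " ", nm), cex = 0.7)
  invisible(x)
}
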