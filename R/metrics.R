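# Validate a prediction matrix against the actual outcomes and return the
# per-case probability of the correct state (P_c).
.pc <- function(pred, actual) {
  pred <- as.matrix(pred)
  if (is.null(colnames(pred)))
    stop("prediction matrix needs state labels as column names", call. = FALSE)
  if (!nrow(pred)) stop("no predictions", call. = FALSE)
  if (length(actual) != nrow(pred))
    stop("one actual state per prediction required", call. = FALSE)
  j <- match(as.character(actual), colnames(pred))
  if (anyNA(j)) stop("actual state not among prediction columns", call. = FALSE)
  if (any(abs(rowSums(pred) - 1) > 1e-6))
    stop("each predicted distribution must sum to 1", call. = FALSE)
  pred[cbind(seq_len(nrow(pred)), j)]
}

#' Confusion matrix and error rate
#'
#' The predicted label of a case is the state with the highest predicted
#' probability; ties are broken in favour of the first state in the state
#' order (for the NSI outcome, ordered `(yes, no)`, a 50/50 prediction is
#' therefore classified as `"yes"` -- the conservative call for a
#' safety-critical outcome).  The error rate is
#' `100 * (misclassified cases) / n`.
#'
#' @param pred Matrix of predicted distributions (rows = cases, columns
#'   named by state).
#' @param actual Character vector of observed states.
#' @return List with `confusion` (actual x predicted table) and
#'   `error_rate` (percent).
#' @export
confusion_and_error_rate <- function(pred, actual) {
  .pc(pred, actual)  # validation
  states <- colnames(pred)
  predicted <- states[apply(pred, 1L, which.max)]  # which.max: first of ties
  confusion <- table(factor(actual, levels = states),
                     factor(predicted, levels = states),
                     dnn = c("actual", "predicted"))
  list(confusion = confusion,
       error_rate = 100 * mean(predicted != actual))
}

#' Logarithmic loss
#'
#' Mean over cases of `-log(P_c)`, where `P_c` is the predicted probability
#' of the state that actually occurred.  Natural logarithm by default; 0
#' for perfect predictions, unbounded above.
#'
#' @inheritParams confusion_and_error_rate
#' @param base Logarithm base (default `exp(1)`).
#' @return Mean logarithmic loss.
#' @export
logarithmic_loss <- function(pred, actual, base = exp(1)) {
  pc <- .pc(pred, actual)
  if (any(pc <= 0))
    stop("a correct state was predicted with probability 0; ",
         "fit with a positive pseudocount", call. = FALSE)
  mean(-log(pc, base = base))
}

#' Quadratic (Brier) loss
#'
#' Mean over cases of `1 - 2 * P_c + sum_j P_j^2`; ranges from 0 (perfect)
#' to 2.  For a binary outcome this equals twice the mean Brier score of
#' the predicted probability of either state.
#'
#' @inheritParams confusion_and_error_rate
#' @return Mean quadratic loss.
#' @export
quadratic_loss <- function(pred, actual) {
  pc <- .pc(pred, actual)
  mean(1 - 2 * pc + rowSums(as.matrix(pred)^2))
}

#' Spherical payoff
#'
#' Mean over cases of `P_c / sqrt(sum_j P_j^2)`; ranges from 0 to 1, higher
#' is better.
#'
#' @inheritParams confusion_and_error_rate
#' @return Mean spherical payoff.
#' @export
spherical_payoff <- function(pred, actual) {
  pc <- .pc(pred, actual)
  mean(pc / sqrt(rowSums(as.matrix(pred)^2)))
}

#' Score a model on held-out cases
#'
#' Predicts the outcome posterior for every test record from its
#' non-missing predictor values and assembles the four validation indices:
#' error rate (from the confusion matrix), logarithmic loss, quadratic
#' loss and spherical payoff.  Records with a missing outcome are skipped
#' with a warning.
#'
#' @param model A fitted `hfacs_bn` model.
#' @param test Data frame of discretized test records including the
#'   outcome column.
#' @param outcome Outcome variable name (default `"nsi"`).
#' @return Object of class `bn_performance`: list with `confusion`,
#'   `error_rate`, `logarithmic_loss`, `quadratic_loss`,
#'   `spherical_payoff`, `n`, and the prediction matrix `predictions`.
#' @export
evaluate_model <- function(model, test, outcome = "nsi") {
  model <- .as_model(model)
  if (!outcome %in% colnames(test))
    stop("test data lacks the outcome column '", outcome, "'", call. = FALSE)
  actual <- as.character(test[[outcome]])
  usable <- which(!is.na(actual))
  if (length(usable) < nrow(test))
    warning(nrow(test) - length(usable),
            " record(s) with missing outcome skipped", call. = FALSE)
  if (!length(usable)) stop("no test records with observed outcome",
                            call. = FALSE)
  predictors <- setdiff(colnames(test), outcome)
  states <- model$structure$variables[[outcome]]$states
  pred <- t(vapply(usable, function(i) {
    as.numeric(predict_case(model, test[i, predictors, drop = FALSE], outcome))
  }, numeric(length(states))))
  colnames(pred) <- states
  actual <- actual[usable]
  ce <- confusion_and_error_rate(pred, actual)
  structure(list(confusion = ce$confusion, error_rate = ce$error_rate,
                 logarithmic_loss = logarithmic_loss(pred, actual),
                 quadratic_loss = quadratic_loss(pred, actual),
                 spherical_payoff = spherical_payoff(pred, actual),
                 n = length(usable), predictions = pred, actual = actual),
            class = "bn_performance")
}

#' @export
print.bn_performance <- function(x, ...) {
  cat("Model performance on", x$n, "test cases\n\n")
  cat(sprintf("  %-22s %8s   %s\n", "Index", "Value", "Range"))
  cat(sprintf("  %-22s %8.2f   0-100 (lower is better)\n",
              "Total error rate (%)", x$error_rate))
  cat(sprintf("  %-22s %8.2f   0-Inf (lower is better)\n",
              "Logarithmic loss", x$logarithmic_loss))
  cat(sprintf("  %-22s %8.2f   0-2   (lower is better)\n",
              "Quadratic loss", x$quadratic_loss))
  cat(sprintf("  %-22s %8.2f   0-1   (higher is better)\n",
              "Spherical payoff", x$spherical_payoff))
  cat("\nConfusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
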