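#' Names of the Likert item columns
#'
#' The questionnaire CSV dialect stores the items of each multi-item scale
#' in columns `<scale>_i<j>` (e.g. `fatigue_i1` ... `fatigue_i4`; the
#' management-commitment scale has five items), and the directly asked
#' variables in columns named after the variable itself.
#'
#' @param catalog A `bn_catalog` (default the 12-variable study catalog).
#' @return Named list mapping each multi-item scale to its item column
#'   names.
#' @export
likert_item_columns <- function(catalog = hfacs_variables()) {
  catalog <- .as_catalog(catalog)
  scales <- Filter(function(v) v$measurement == "multi_item_scale", catalog)
  stats::setNames(
    lapply(scales, function(v) paste0(v$name, "_i", seq_len(v$n_items))),
    vapply(scales, `[[`, character(1), "name"))
}

#' Score a multi-item Likert scale
#'
#' The scale score is the arithmetic mean of the item responses.  Missing
#' items are tolerated as long as at least `min_frac` of the items were
#' answered; otherwise the score is `NA` (the residual missingness is
#' handled downstream by EM).
#'
#' @param items Numeric vector of item responses (integers 1-5, `NA`
#'   allowed).
#' @param min_frac Minimum answered fraction required (default 0.5).
#' @return Scale score in `[1, 5]`, or `NA`.
#' @examples
#' score_scale(c(1, 2, 4, 5))      # 3
#' score_scale(c(5, NA, 4, 5))     # 14/3
#' @export
score_scale <- function(items, min_frac = 0.5) {
  ok <- !is.na(items)
  if (any(items[ok] %% 1 != 0 | items[ok] < 1 | items[ok] > 5))
    stop("item responses must be integers in 1..5", call. = FALSE)
  if (sum(ok) < min_frac * length(items) || !sum(ok)) return(NA_real_)
  mean(items[ok])
}

#' Discretize a raw value into a variable state
#'
#' Applies the study's discretization rules:
#' \describe{
#'   \item{`scale_terciles`}{The Likert score range `[1, 5]` split into
#'     three equal intervals: `[1, 7/3)`, `[7/3, 11/3)`, `[11/3, 5]`
#'     (closed on the left, top interval closed at 5).}
#'   \item{`working_hours`}{`< 45` normal, `45-55` high, `> 55` very high.}
#'   \item{`night_shifts`}{`<= 8` normal, `9-11` high, `>= 12` very high.}
#'   \item{`binary`}{Direct yes/no answers pass through after validation.}
#' }
#' Passing a state label to a numeric rule is an error, not a no-op:
#' discretization is defined on raw answers only.
#'
#' @param variable A [bn_variable()] or a variable name looked up in
#'   `catalog`.
#' @param value Vector of raw values.
#' @param catalog Catalog used to resolve `variable` by name.
#' @return Character vector of state labels (`NA` for missing input).
#' @examples
#' discretize_value("working_hours", c(44, 45, 55, 56))
#' discretize_value("night_shifts", c(8, 9, 11, 12))
#' discretize_value("fatigue", 7/3)   # "moderate"
#' @export
discretize_value <- function(variable, value, catalog = hfacs_variables()) {
  if (is.character(variable)) {
    variable <- catalog[[variable]] %||%
      stop("unknown variable '", variable, "'", call. = FALSE)
  }
  stopifnot(inherits(variable, "bn_variable"))
  rule <- variable$discretization
  states <- variable$states
  if (identical(rule, "binary")) {
    value <- as.character(value)
    bad <- !is.na(value) & !(value %in% states)
    if (any(bad))
      stop("illegal value(s) for '", variable$name, "': ",
           paste(unique(value[bad]), collapse = ", "), call. = FALSE)
    return(value)
  }
  if (!is.numeric(value))
    stop("raw value for '", variable$name, "' must be numeric", call. = FALSE)
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  x <- value[ok]
  idx <- switch(rule,
    scale_terciles = {
      if (any(x < 1 | x > 5))
        stop("scale score outside [1, 5]", call. = FALSE)
      ifelse(x < 7 / 3, 1L, ifelse(x < 11 / 3, 2L, 3L))
    },
    working_hours = {
      if (any(x < 0)) stop("working hours must be non-negative", call. = FALSE)
      ifelse(x < 45, 1L, ifelse(x <= 55, 2L, 3L))
    },
    night_shifts = {
      if (any(x < 0 | x %% 1 != 0))
        stop("night shifts must be a non-negative integer", call. = FALSE)
      ifelse(x <= 8, 1L, ifelse(x <= 11, 2L, 3L))
    },
    stop("unknown discretization rule '", rule, "'", call. = FALSE))
  out[ok] <- states[idx]
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(item sums))`,
#' computed on listwise-complete rows with sample variances.
#'
#' @param items Numeric matrix or data frame, respondents x items.
#' @return Alpha (a value `<= 1`).  Signals an error when fewer than two
#'   complete rows or items are available, or when the total score has zero
#'   variance (alpha undefined).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items", call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 complete respondents", call. = FALSE)
  vt <- stats::var(rowSums(m))
  if (vt == 0)
    stop("total score has zero variance; alpha is undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Flag straight-lining respondents
#'
#' A respondent is flagged as a systematic (straight-lining) responder when
#' every Likert item across the whole questionnaire was answered and all
#' answers are identical -- zero response variance, the signature of
#' pattern-filling without reading the questions.
#'
#' @param raw Data frame of raw questionnaire records.
#' @param catalog A `bn_catalog`.
#' @return Logical vector, one flag per record.
#' @export
detect_straightlining <- function(raw, catalog = hfacs_variables()) {
  cols <- unlist(likert_item_columns(catalog), use.names = FALSE)
  miss <- setdiff(cols, colnames(raw))
  if (length(miss))
    stop("raw data is missing item column(s): ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) " ...", call. = FALSE)
  m <- as.matrix(raw[, cols])
  apply(m, 1L, function(x) !anyNA(x) && length(unique(x)) == 1L)
}

#' Preprocess raw questionnaire records
#'
#' The full ingestion pipeline of the study: discard straight-lining
#' respondents, average each multi-item scale into a score, compute
#' per-scale Cronbach alphas on the retained records, discretize every
#' variable into its ordered states, and report what happened.  Records
#' with a missing outcome are retained (EM can use them for training; model
#' scoring skips them).
#'
#' @param raw Data frame in the questionnaire CSV dialect (see
#'   [likert_item_columns()]; direct answers in columns
#'   `night_shifts`, `working_hours`, `safe_procedures`, `nsi`).
#' @param catalog A `bn_catalog`.
#' @param min_frac Minimum answered fraction per scale (see
#'   [score_scale()]).
#' @return An object of class `nsi_preprocess`: list with `data` (the
#'   discretized dataset, one state-label column per variable), `kept`
#'   (row indices of retained records), `flags` (straight-lining flags) and
#'   `report` (counts received/discarded/retained, per-scale alpha, counts
#'   of malformed values coerced to missing).
#' @export
preprocess_questionnaire <- function(raw, catalog = hfacs_variables(),
                                     min_frac = 0.5) {
  catalog <- .as_catalog(catalog)
  if (!nrow(raw)) {
    warning("empty input: no records to preprocess", call. = FALSE)
    nm <- names(catalog)
    empty <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(nm)), nm), stringsAsFactors = FALSE)
    return(structure(list(data = empty, kept = integer(0), flags = logical(0),
                          report = list(received = 0L, discarded = 0L,
                                        retained = 0L, alphas = numeric(0),
                                        malformed = 0L)),
                     class = "nsi_preprocess"))
  }
  flags <- detect_straightlining(raw, catalog)
  kept <- which(!flags)
  keptraw <- raw[kept, , drop = FALSE]
  items <- likert_item_columns(catalog)

  alphas <- vapply(names(items), function(sc) {
    tryCatch(cronbach_alpha(keptraw[, items[[sc]]]),
             error = function(e) NA_real_)
  }, numeric(1))

  malformed <- 0L
  grab <- function(expr) {
    # coerce malformed direct answers to missing, counting them
    tryCatch(expr, error = function(e) NULL)
  }
  out <- stats::setNames(vector("list", length(catalog)), names(catalog))
  for (v in names(catalog)) {
    spec <- catalog[[v]]
    if (spec$measurement == "multi_item_scale") {
      sc <- apply(as.matrix(keptraw[, items[[v]]]), 1L, function(x)
        tryCatch(score_scale(x, min_frac), error = function(e) NA_real_))
      out[[v]] <- discretize_value(spec, sc)
    } else {
      x <- keptraw[[v]]
      if (is.null(x)) stop("raw data is missing column '", v, "'",
                           call. = FALSE)
      lab <- rep(NA_character_, length(x))
      for (i in seq_along(x)) {
        val <- if (spec$discretization == "binary") as.character(x[[i]])
               else suppressWarnings(as.numeric(x[[i]]))
        if (is.na(val) && !is.na(x[[i]]) && nzchar(as.character(x[[i]])))
          malformed <- malformed + 1L
        lab[i] <- grab(discretize_value(spec, val)) %||% {
          malformed <- malformed + 1L
          NA_character_
        }
      }
      out[[v]] <- lab
    }
  }
  data <- as.data.frame(out, stringsAsFactors = FALSE)
  if ("respondent_id" %in% colnames(raw))
    rownames(data) <- raw$respondent_id[kept]
  structure(list(
    data = data, kept = kept, flags = flags,
    report = list(received = nrow(raw), discarded = sum(flags),
                  retained = length(kept), alphas = alphas,
                  malformed = malformed)),
    class = "nsi_preprocess")
}

#' @export
print.nsi_preprocess <- function(x, ...) {
  r <- x$report
  cat("Questionnaire preprocessing\n")
  cat(sprintf("  received %d, discarded %d (straight-lining), retained %d\n",
              r$received, r$discarded, r$retained))
  if (r$malformed) cat("  malformed values coerced to missing:", r$malformed, "\n")
  if (length(r$alphas)) {
    cat("  Cronbach alpha by scale:\n")
    for (s in names(r$alphas))
      cat(sprintf("    %-22s %.2f\n", s, r$alphas[[s]]))
  }
  invisible(x)
}

#' Split a discretized dataset into training and test sets
#'
#' Sampling is random without replacement under the given seed.  When the
#' dataset holds at least 393 records the study sizes (343 train, 50 test)
#' are used and any surplus records are left unused; smaller datasets are
#' split in the same 343:50 proportion (train size rounded, remainder to
#' test).
#'
#' @param data Discretized data frame.
#' @param seed Integer seed for the split.
#' @param train_size,test_size Optional explicit sizes overriding the rule.
#' @return List with `train`, `test`, `unused` (data frames) and `sizes`.
#' @export
split_train_test <- function(data, seed = 1L, train_size = NULL,
                             test_size = NULL) {
  n <- nrow(data)
  if (is.null(train_size) || is.null(test_size)) {
    if (n >= 393L) {
      train_size <- 343L; test_size <- 50L
    } else {
      train_size <- as.integer(round(n * 343 / 393))
      test_size <- n - train_size
    }
  }
  if (train_size + test_size > n)
    stop("requested split larger than the dataset", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  tr <- sort(idx[seq_len(train_size)])
  te <- sort(idx[train_size + seq_len(test_size)])
  un <- sort(idx[-(seq_len(train_size + test_size))])
  list(train = data[tr, , drop = FALSE], test = data[te, , drop = FALSE],
       unused = data[un, , drop = FALSE],
       sizes = c(train = train_size, test = test_size,
                 unused = n - train_size - test_size))
}

#' Write a discretized dataset as CSV with a provenance header
#'
#' @param data Data frame of state labels.
#' @param path Output file.
#' @param provenance Optional named list stamped into a leading `#` comment
#'   line (e.g. seed and configuration hash).
#' @return `path`, invisibly.
#' @export
write_discrete_csv <- function(data, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# provenance: ",
                      paste(names(provenance), unlist(provenance),
                            sep = "=", collapse = " ")), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' Read a questionnaire or discretized CSV
#'
#' Reads the package's CSV dialect (UTF-8, empty cell = missing, optional
#' leading `#` provenance comment).
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_questionnaire_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", na.strings = c("", "NA"),
                  stringsAsFactors = FALSE)
}
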