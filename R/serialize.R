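#' Serialize a model to JSON
#'
#' Documented schema: `variables` (name, level, states, measurement,
#' n_items, discretization), `parents` (node -> ordered parent list), and
#' `cpts` (node -> list of rows in canonical parent-configuration order,
#' last parent fastest).  Fitted models additionally carry `fit`
#' (log-likelihood, trace, iterations, convergence, settings).
#'
#' @param model An `hfacs_bn` model.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @param provenance Optional named list stored under `provenance`.
#' @return `path` (invisibly) or a JSON string.
#' @export
bn_write_json <- function(model, path = NULL, provenance = NULL) {
  model <- .as_model(model)
  drop_na <- function(x) if (length(x) == 1L && is.na(x)) NULL else x
  vars <- lapply(model$structure$variables, function(v)
    list(name = v$name, level = drop_na(v$level), states = v$states,
         measurement = v$measurement, n_items = drop_na(v$n_items),
         discretization = drop_na(v$discretization)))
  obj <- list(
    format = "hfacsbn-model/1",
    variables = unname(vars),
    parents = model$structure$parents,
    cpts = lapply(model$cpts, function(m)
      lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))))
  if (!is.null(model$loglik))
    obj$fit <- list(loglik = model$loglik, trace = model$trace,
                    objective_trace = model$objective_trace,
                    iterations = model$iterations,
                    converged = model$converged, n = model$n,
                    settings = model$settings)
  if (!is.null(provenance)) obj$provenance <- provenance
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path File or JSON string produced by [bn_write_json()].
#' @return An `hfacs_bn` model (with fit information when present).
#' @export
bn_read_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "hfacsbn-model/1"))
    stop("not an hfacsbn model file", call. = FALSE)
  vars <- lapply(obj$variables, function(v)
    bn_variable(v$name, unlist(v$states), v$level %||% NA_integer_,
                v$measurement, v$n_items %||% NA_integer_,
                v$discretization %||% NA_character_))
  names(vars) <- vapply(vars, `[[`, character(1), "name")
  class(vars) <- "bn_catalog"
  parents <- lapply(obj$parents, function(p) as.character(unlist(p)))
  structure_ <- bn_structure(vars, parents)
  cpts <- lapply(names(vars), function(v) {
    rows <- obj$cpts[[v]]
    m <- do.call(rbind, lapply(rows, unlist))
    colnames(m) <- vars[[v]]$states
    m
  })
  names(cpts) <- names(vars)
  model <- hfacs_bn(structure_, cpts)
  if (!is.null(obj$fit)) {
    model$loglik <- obj$fit$loglik
    model$trace <- unlist(obj$fit$trace)
    model$objective_trace <- unlist(obj$fit$objective_trace)
    model$iterations <- obj$fit$iterations
    model$converged <- obj$fit$converged
    model$n <- obj$fit$n
    model$settings <- obj$fit$settings
  }
  model
}

#' Export a model in XMLBIF 0.3 interchange format
#'
#' Writes the network in the XMLBIF 0.3 dialect understood by standard
#' Bayesian-network tools.  Table entries are listed in canonical order:
#' parent configurations with the last `GIVEN` parent varying fastest, and
#' the child outcomes within each configuration.
#'
#' @param model An `hfacs_bn` model.
#' @param path Output file.
#' @param name Network name attribute.
#' @return `path`, invisibly.
#' @export
bn_write_xmlbif <- function(model, path, name = "hfacs_nsi") {
  model <- .as_model(model)
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<BIF VERSION="0.3">', "<NETWORK>",
             sprintf("<NAME>%s</NAME>", esc(name)))
  for (v in model$structure$variables) {
    lines <- c(lines, '<VARIABLE TYPE="nature">',
               sprintf("  <NAME>%s</NAME>", esc(v$name)),
               sprintf("  <OUTCOME>%s</OUTCOME>", esc(v$states)),
               "</VARIABLE>")
  }
  for (v in names(model$structure$variables)) {
    pa <- model$structure$parents[[v]]
    tab <- paste(sprintf("%.17g", as.vector(t(model$cpts[[v]]))),
                 collapse = " ")
    lines <- c(lines, "<DEFINITION>",
               sprintf("  <FOR>%s</FOR>", esc(v)),
               if (length(pa)) sprintf("  <GIVEN>%s</GIVEN>", esc(pa)),
               sprintf("  <TABLE>%s</TABLE>", tab),
               "</DEFINITION>")
  }
  lines <- c(lines, "</NETWORK>", "</BIF>")
  writeLines(lines, path)
  invisible(path)
}
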