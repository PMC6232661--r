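#' Define a discrete network variable
#'
#' Creates the specification of one node of a discrete Bayesian network: its
#' name, its ordered states, the HFACS level it sits on (4 = organizational
#' influences, 3 = unsafe supervision, 2 = preconditions for unsafe acts,
#' 1 = outcome), how it is measured by the questionnaire, and which
#' discretization rule turns a raw answer into a state.
#'
#' @param name Variable name (single string, used as a column name).
#' @param states Character vector of ordered state labels (at least two).
#' @param level Integer HFACS level, or `NA` for fixture variables that do
#'   not belong to the layered model.
#' @param measurement One of `"multi_item_scale"`, `"direct_numeric"`,
#'   `"direct_binary"`.
#' @param n_items Number of Likert items for multi-item scales.
#' @param discretization Name of the discretization rule
#'   (see [discretize_value()]).
#' @return An object of class `bn_variable`.
#' @seealso [hfacs_variables()] for the full study catalog.
#' @export
bn_variable <- function(name, states, level = NA_integer_,
                        measurement = c("multi_item_scale", "direct_numeric",
                                        "direct_binary"),
                        n_items = NA_integer_,
                        discretization = NA_character_) {
  .assert_scalar_chr(name, "name")
  if (!is.character(states) || length(states) < 2L || anyDuplicated(states))
    stop("'states' must be >= 2 distinct labels", call. = FALSE)
  measurement <- match.arg(measurement)
  structure(
    list(name = name, states = states, level = as.integer(level),
         measurement = measurement, n_items = as.integer(n_items),
         discretization = discretization),
    class = "bn_variable")
}

#' The HFACS variable catalog for needlestick and sharps injuries
#'
#' Returns the catalog of the 12 study variables in canonical order:
#' three organizational-influence variables (level 4), four
#' unsafe-supervision variables (level 3), four precondition variables
#' (level 2) and the NSI outcome (level 1).  All Likert-scale variables and
#' the two scheduling variables have three ordered states; the availability
#' of safe work procedures and the NSI outcome are binary.
#'
#' The state order follows the questionnaire coding (e.g. `poor < moderate
#' < good`); the outcome is ordered `(yes, no)` so that the favourable
#' `"no"` state is always addressable as the second state.
#'
#' @return An object of class `bn_catalog`: a named list of
#'   [bn_variable()] specifications.
#' @examples
#' cat12 <- hfacs_variables()
#' length(cat12)           # 12
#' cat12$fatigue$states    # low, moderate, high
#' @export
hfacs_variables <- function() {
  v <- list(
    bn_variable("management_commitment", c("poor", "moderate", "good"), 4L,
                "multi_item_scale", 5L, "scale_terciles"),
    bn_variable("staffing", c("poor", "moderate", "good"), 4L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("safe_procedures", c("yes", "no"), 4L,
                "direct_binary", NA_integer_, "binary"),
    bn_variable("night_shifts", c("normal", "high", "very_high"), 3L,
                "direct_numeric", NA_integer_, "night_shifts"),
    bn_variable("working_hours", c("normal", "high", "very_high"), 3L,
                "direct_numeric", NA_integer_, "working_hours"),
    bn_variable("supervisor_attitude", c("poor", "moderate", "good"), 3L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("safety_training", c("poor", "moderate", "good"), 3L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("fatigue", c("low", "moderate", "high"), 2L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("teamwork", c("poor", "moderate", "good"), 2L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("physical_environment", c("poor", "moderate", "good"), 2L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("safety_motivation", c("poor", "moderate", "good"), 2L,
                "multi_item_scale", 4L, "scale_terciles"),
    bn_variable("nsi", c("yes", "no"), 1L,
                "direct_binary", NA_integer_, "binary")
  )
  names(v) <- vapply(v, `[[`, character(1), "name")
  class(v) <- "bn_catalog"
  v
}

.as_catalog <- function(variables) {
  if (inherits(variables, "bn_catalog")) return(variables)
  if (is.list(variables) && all(vapply(variables, inherits, TRUE, "bn_variable"))) {
    names(variables) <- vapply(variables, `[[`, character(1), "name")
    class(variables) <- "bn_catalog"
    return(variables)
  }
  stop("'variables' must be a bn_catalog or list of bn_variable objects",
       call. = FALSE)
}

#' Construct a discrete Bayesian-network structure
#'
#' Generic constructor: any directed acyclic graph over a variable catalog.
#' Used for test fixtures and custom topologies; the layered HFACS network of
#' the NSI study is built by [hfacs_structure()].
#'
#' @param variables A `bn_catalog` (or list of [bn_variable()]).
#' @param parents Named list mapping node name to the ordered character
#'   vector of its parents.  Nodes absent from the list are roots.
#' @return An object of class `bn_structure` with elements `variables` and
#'   `parents` (one entry per node, canonical order).
#' @export
bn_structure <- function(variables, parents = list()) {
  variables <- .as_catalog(variables)
  nm <- names(variables)
  if (anyDuplicated(nm)) stop("duplicate variable names", call. = FALSE)
  if (length(parents)) {
    bad <- setdiff(names(parents), nm)
    if (length(bad)) stop("parents given for unknown node(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(vector("list", length(nm)), nm)
  for (v in nm) {
    p <- parents[[v]] %||% character(0)
    if (!all(p %in% nm)) stop("unknown parent of '", v, "'", call. = FALSE)
    if (v %in% p) stop("node '", v, "' cannot be its own parent", call. = FALSE)
    if (anyDuplicated(p)) stop("duplicate parents of '", v, "'", call. = FALSE)
    full[[v]] <- p
  }
  .topo_sort(full)  # errors on cycles
  structure(list(variables = variables, parents = full),
            class = "bn_structure")
}

#' Build the layered HFACS network structure
#'
#' Constructs the directed acyclic graph implied by the two HFACS structural
#' assumptions: variables within one level are not connected, and every
#' variable of a level is a parent of every variable in the immediately lower
#' level.  With the 12-variable catalog this yields 32 edges
#' (3x4 + 4x4 + 4x1) and a single sink, the NSI outcome.
#'
#' @param catalog A `bn_catalog` whose variables carry HFACS levels covering
#'   every level from the outcome up to the top level present.
#' @return A `bn_structure`.
#' @examples
#' net <- hfacs_structure()
#' length(net$parents$nsi)   # 4
#' @export
hfacs_structure <- function(catalog = hfacs_variables()) {
  catalog <- .as_catalog(catalog)
  lv <- vapply(catalog, `[[`, integer(1), "level")
  if (anyNA(lv)) stop("all catalog variables need an HFACS level", call. = FALSE)
  levels_present <- sort(unique(lv))
  if (!identical(levels_present, seq(min(lv), max(lv))) || length(levels_present) < 2L)
    stop("catalog must cover a contiguous range of HFACS levels", call. = FALSE)
  nm <- names(catalog)
  by_level <- split(nm, lv)  # within-level order = catalog order
  parents <- list()
  for (L in rev(levels_present[-length(levels_present)])) {
    upper <- by_level[[as.character(L + 1L)]]
    for (child in by_level[[as.character(L)]]) parents[[child]] <- upper
  }
  bn_structure(catalog, parents)
}

#' @export
print.bn_structure <- function(x, ...) {
  lv <- vapply(x$variables, `[[`, integer(1), "level")
  cat("Discrete Bayesian-network structure\n")
  cat("  nodes:", length(x$variables),
      " edges:", sum(vapply(x$parents, length, 0L)), "\n")
  if (!anyNA(lv)) {
    for (L in sort(unique(lv), decreasing = TRUE))
      cat(sprintf("  level %d: %s\n", L,
                  paste(names(x$variables)[lv == L], collapse = ", ")))
  }
  invisible(x)
}

#' Edge list of a network structure
#'
#' @param structure A `bn_structure`.
#' @return A data frame with columns `from` and `to`, one row per edge.
#' @export
bn_edges <- function(structure) {
  out <- do.call(rbind, lapply(names(structure$parents), function(v) {
    p <- structure$parents[[v]]
    if (!length(p)) return(NULL)
    data.frame(from = p, to = v, stringsAsFactors = FALSE)
  }))
  out %||% data.frame(from = character(0), to = character(0))
}

.n_states <- function(structure, v) length(structure$variables[[v]]$states)

.cards <- function(structure, vars = names(structure$variables))
  vapply(vars, .n_states, integer(1), structure = structure)

.n_parent_configs <- function(structure, v) {
  p <- structure$parents[[v]]
  if (!length(p)) 1L else as.integer(prod(.cards(structure, p)))
}

#' Canonical parent-configuration index
#'
#' Parent configurations are numbered by a mixed-radix scheme over the
#' ordered parent list with the *last* parent varying fastest; this is the
#' row order of every conditional probability table (CPT) in the package and
#' of all serialized output.
#'
#' @param structure A `bn_structure`.
#' @param node Node name.
#' @param parent_states Character vector of parent states in canonical
#'   parent order, or a character matrix / data frame with one row per
#'   configuration.
#' @return Integer vector of 1-based configuration indices.
#' @export
parent_config_index <- function(structure, node, parent_states) {
  p <- structure$parents[[node]]
  if (is.null(p)) stop("unknown node '", node, "'", call. = FALSE)
  if (!length(p)) return(1L)
  if (is.data.frame(parent_states)) parent_states <- as.matrix(parent_states)
  if (is.null(dim(parent_states))) parent_states <- matrix(parent_states, nrow = 1L)
  if (ncol(parent_states) != length(p))
    stop("expected ", length(p), " parent states", call. = FALSE)
  idx <- matrix(0L, nrow(parent_states), length(p))
  for (j in seq_along(p)) {
    idx[, j] <- match(parent_states[, j], structure$variables[[p[j]]]$states)
    if (anyNA(idx[, j]))
      stop("illegal state for parent '", p[j], "'", call. = FALSE)
  }
  .mixed_radix(idx, .cards(structure, p))
}

#' Enumerate parent configurations in canonical order
#'
#' @param structure A `bn_structure`.
#' @param node Node name.
#' @param labels Return state labels (`TRUE`) or integer indices.
#' @return A matrix with one row per configuration (canonical order) and one
#'   column per parent; zero-column, one-row matrix for root nodes.
#' @export
parent_config_table <- function(structure, node, labels = TRUE) {
  p <- structure$parents[[node]]
  if (is.null(p)) stop("unknown node '", node, "'", call. = FALSE)
  if (!length(p)) {
    m <- matrix(integer(0), nrow = 1L, ncol = 0L)
    return(m)
  }
  card <- .cards(structure, p)
  # last parent fastest
  grid <- as.matrix(rev(expand.grid(rev(lapply(card, seq_len)),
                                    KEEP.OUT.ATTRS = FALSE)))
  colnames(grid) <- p
  if (!labels) return(grid)
  out <- grid
  mode(out) <- "character"
  for (j in seq_along(p)) out[, j] <- structure$variables[[p[j]]]$states[grid[, j]]
  out
}

#' Uniform conditional probability tables
#'
#' @param structure A `bn_structure`.
#' @return Named list of CPT matrices (rows = canonical parent
#'   configurations, columns = child states), every row uniform.
#' @export
uniform_cpts <- function(structure) {
  out <- lapply(names(structure$variables), function(v) {
    k <- .n_states(structure, v)
    matrix(1 / k, nrow = .n_parent_configs(structure, v), ncol = k,
           dimnames = list(NULL, structure$variables[[v]]$states))
  })
  stats::setNames(out, names(structure$variables))
}

#' Random conditional probability tables
#'
#' Draws every CPT row independently from a symmetric Dirichlet
#' distribution; used for seeded test fixtures and oracle comparisons.
#'
#' @param structure A `bn_structure`.
#' @param seed Optional integer seed.
#' @param alpha Dirichlet concentration (default 1 = flat).
#' @return Named list of CPT matrices.
#' @export
random_cpts <- function(structure, seed = NULL, alpha = 1) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(structure$variables), function(v) {
    k <- .n_states(structure, v)
    nc <- .n_parent_configs(structure, v)
    g <- matrix(stats::rgamma(nc * k, shape = alpha), nrow = nc)
    g <- g / rowSums(g)
    dimnames(g) <- list(NULL, structure$variables[[v]]$states)
    g
  })
  stats::setNames(out, names(structure$variables))
}

#' Validate a CPT set against its structure
#'
#' Checks, for every node, that the table has the required dimensions, that
#' all entries lie in `[0, 1]`, and that every row (one fixed parent
#' configuration) sums to 1 within `tol`.
#'
#' @param structure A `bn_structure`.
#' @param cpts Named list of CPT matrices.
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return A data frame of violations with columns `node`, `config`, `type`
#'   and `message`; zero rows if and only if the CPT set is valid.
#' @export
validate_cpts <- function(structure, cpts, tol = 1e-9) {
  bad <- list()
  note <- function(node, config, type, message)
    bad[[length(bad) + 1L]] <<- data.frame(node = node, config = config,
                                           type = type, message = message,
                                           stringsAsFactors = FALSE)
  for (v in names(structure$variables)) {
    m <- cpts[[v]]
    if (is.null(m)) { note(v, NA_integer_, "missing", "no CPT"); next }
    k <- .n_states(structure, v); nc <- .n_parent_configs(structure, v)
    if (!is.matrix(m) || nrow(m) != nc || ncol(m) != k) {
      note(v, NA_integer_, "size",
           sprintf("expected %d x %d table, got %s x %s", nc, k,
                   NROW(m), NCOL(m)))
      next
    }
    out_of_range <- which(m < 0 | m > 1 | !is.finite(m), arr.ind = TRUE)
    if (nrow(out_of_range))
      for (i in unique(out_of_range[, 1L]))
        note(v, i, "range", "entry outside [0, 1]")
    rs <- rowSums(m)
    off <- which(abs(rs - 1) > tol)
    for (i in off)
      note(v, i, "rowsum", sprintf("row sums to %.6g", rs[i]))
  }
  if (!length(bad))
    return(data.frame(node = character(0), config = integer(0),
                      type = character(0), message = character(0)))
  do.call(rbind, bad)
}

#' Total number of CPT entries in a structure
#'
#' For the layered 12-variable HFACS network this is
#' `3 + 3 + 2 + 4*54 + 4*243 + 162 = 1358`, with the largest single table
#' (a three-state precondition node with four three-state parents) holding
#' `3^5 = 243` entries -- the figure that sets the minimum number of training
#' cases for the study design.
#'
#' @param structure A `bn_structure`.
#' @param per_node Return the per-node vector instead of the total.
#' @return Integer count (or named integer vector).
#' @export
bn_parameter_count <- function(structure, per_node = FALSE) {
  n <- vapply(names(structure$variables), function(v)
    .n_parent_configs(structure, v) * .n_states(structure, v), integer(1))
  if (per_node) n else sum(n)
}

#' Joint probability of a full assignment
#'
#' Chain-rule factorization: the product over nodes of
#' `P(state | parent states)` read off the CPTs.
#'
#' @param structure A `bn_structure`.
#' @param cpts Named list of CPT matrices.
#' @param assignment Named character vector (or list) giving a state for
#'   every variable.
#' @return A single probability.
#' @export
joint_probability <- function(structure, cpts, assignment) {
  assignment <- unlist(assignment)
  nm <- names(structure$variables)
  miss <- setdiff(nm, names(assignment))
  if (length(miss))
    stop("assignment is missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- vapply(nm, function(v) {
    i <- match(assignment[[v]], structure$variables[[v]]$states)
    if (is.na(i)) stop("illegal state '", assignment[[v]], "' for '", v, "'",
                       call. = FALSE)
    i
  }, integer(1))
  p <- 1
  for (v in nm) {
    pa <- structure$parents[[v]]
    conf <- if (length(pa)) .mixed_radix(matrix(idx[pa], nrow = 1L),
                                         .cards(structure, pa)) else 1L
    p <- p * cpts[[v]][conf, idx[[v]]]
  }
  unname(p)
}

#' Assemble a Bayesian-network model object
#'
#' Bundles a structure and a valid CPT set into an object of class
#' `hfacs_bn`, the common currency of all inference, validation,
#' sensitivity and simulation functions.  Fitted models returned by
#' [em_fit()] carry additional elements (log-likelihood trace, convergence
#' information, settings).
#'
#' @param structure A `bn_structure`.
#' @param cpts Named list of CPT matrices.
#' @return An object of class `hfacs_bn`.
#' @export
hfacs_bn <- function(structure, cpts) {
  viol <- validate_cpts(structure, cpts)
  if (nrow(viol))
    stop("invalid CPT set: ", nrow(viol), " violation(s); first: ",
         viol$node[1], " (", viol$type[1], ") ", viol$message[1],
         call. = FALSE)
  structure(list(structure = structure, cpts = cpts[names(structure$variables)]),
            class = "hfacs_bn")
}

.as_model <- function(model) {
  if (inherits(model, "hfacs_bn")) return(model)
  if (is.list(model) && !is.null(model$structure) && !is.null(model$cpts))
    return(model)
  stop("expected an 'hfacs_bn' model", call. = FALSE)
}
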