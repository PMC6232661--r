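# Encode a data frame of state labels as an integer matrix (NA = missing).
.encode_data <- function(structure, data) {
  nm <- names(structure$variables)
  miss <- setdiff(nm, colnames(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  M <- matrix(NA_integer_, nrow(data), length(nm), dimnames = list(NULL, nm))
  for (v in nm) {
    x <- as.character(data[[v]])
    i <- match(x, structure$variables[[v]]$states)
    bad <- !is.na(x) & is.na(i)
    if (any(bad))
      stop("illegal state(s) for '", v, "': ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    M[, v] <- i
  }
  M
}

# Expand records into explicit completions of their missing values, grouped
# by missingness pattern.  Records with every value missing carry no
# information and are dropped; records with more than max_missing missing
# values are dropped to bound the completion count.
.expand_records <- function(structure, M, max_missing = 8L) {
  card <- .cards(structure)
  obs <- !is.na(M)
  nmiss <- ncol(M) - rowSums(obs)
  drop <- nmiss == ncol(M) | nmiss > max_missing
  keep <- which(!drop)
  pat <- vapply(keep, function(i) paste(which(!obs[i, ]), collapse = ","),
                character(1))
  Alist <- list(); rlist <- list()
  for (p in unique(pat)) {
    rows <- keep[pat == p]
    missv <- if (nzchar(p)) as.integer(strsplit(p, ",", fixed = TRUE)[[1L]])
             else integer(0)
    if (length(missv)) {
      G <- as.matrix(expand.grid(lapply(card[missv], seq_len),
                                 KEEP.OUT.ATTRS = FALSE))
      g <- nrow(G)
    } else g <- 1L
    k <- length(rows)
    A <- M[rows, , drop = FALSE][rep(seq_len(k), each = g), , drop = FALSE]
    if (length(missv)) A[, missv] <- G[rep(seq_len(g), k), , drop = FALSE]
    Alist[[length(Alist) + 1L]] <- A
    rlist[[length(rlist) + 1L]] <- rep(rows, each = g)
  }
  A <- if (length(Alist)) do.call(rbind, Alist) else M[0, , drop = FALSE]
  list(A = A, rid = unlist(rlist) %||% integer(0), kept = keep,
       n_dropped_empty = sum(nmiss == ncol(M)),
       n_dropped_wide = sum(nmiss > max_missing & nmiss < ncol(M)))
}

# Per-node linear indices of each completion row into as.vector(cpt).
.family_indices <- function(structure, A) {
  nm <- names(structure$variables)
  card <- .cards(structure)
  L <- matrix(0L, nrow(A), length(nm), dimnames = list(NULL, nm))
  for (v in nm) {
    pa <- structure$parents[[v]]
    conf <- if (length(pa)) .mixed_radix(A[, pa, drop = FALSE], card[pa])
            else rep(1L, nrow(A))
    L[, v] <- (A[, v] - 1L) * .n_parent_configs(structure, v) + conf
  }
  L
}

#' Maximum-likelihood CPT estimation from complete data
#'
#' Smoothed relative frequencies:
#' `P(x | pa) = (count(x, pa) + pseudocount) / (count(pa) + pseudocount * k)`
#' where `k` is the number of child states.  Parent configurations never
#' seen in the data fall back to the (smoothed) uniform row.
#'
#' @param structure A `bn_structure`.
#' @param data Data frame of state labels, one column per variable, no
#'   missing values.
#' @param pseudocount Dirichlet smoothing constant (default 1).
#' @return Named list of CPT matrices.
#' @export
ml_estimate <- function(structure, data, pseudocount = 1) {
  M <- .encode_data(structure, data)
  if (anyNA(M))
    stop("ml_estimate requires complete data; use em_fit for missing values",
         call. = FALSE)
  L <- .family_indices(structure, M)
  nm <- names(structure$variables)
  out <- stats::setNames(vector("list", length(nm)), nm)
  for (v in nm) {
    nc <- .n_parent_configs(structure, v)
    k <- .n_states(structure, v)
    cnt <- tabulate(L[, v], nbins = nc * k)
    out[[v]] <- .m_step(matrix(cnt, nc, k), pseudocount,
                        structure$variables[[v]]$states)
  }
  out
}

.m_step <- function(cmat, pseudocount, states) {
  k <- ncol(cmat)
  num <- cmat + pseudocount
  den <- rowSums(cmat) + pseudocount * k
  if (pseudocount == 0) {
    zero <- den == 0
    if (any(zero)) { num[zero, ] <- 1; den[zero] <- k }
  }
  m <- num / den
  dimnames(m) <- list(NULL, states)
  m
}

#' Fit the network by expectation-maximization
#'
#' Estimates all CPTs from data that may contain missing values.  The
#' E-step computes, for every record, the exact posterior over its missing
#' values given its observed values under the current parameters (by direct
#' enumeration of the record's completions); the M-step re-estimates every
#' CPT as smoothed relative frequencies of the expected counts.  Iteration
#' stops when the relative change in observed-data log-likelihood falls
#' below `tol` or after `max_iter` iterations.
#'
#' Records with no observed value are dropped (they carry no information);
#' records missing more than `max_missing` values are dropped to bound the
#' size of the completion expansion, and a warning reports both counts.
#'
#' @param structure A `bn_structure` (default: the layered HFACS network).
#' @param data Data frame of state labels; `NA` = missing.  Records missing
#'   the outcome are perfectly usable -- EM marginalizes over it.
#' @param pseudocount Dirichlet smoothing constant used in every M-step
#'   (default 1; keeps all probabilities strictly positive so that
#'   logarithmic-loss scoring is always defined).
#' @param tol Relative log-likelihood convergence tolerance (default
#'   `1e-6`).
#' @param max_iter Maximum EM iterations (default 500).
#' @param init `"uniform"` starts from uniform CPTs; `"random"` from a
#'   seeded Dirichlet draw (multi-start exploration).
#' @param seed Seed for `init = "random"`.
#' @param max_missing Maximum number of missing values per record.
#' @param verbose Print the log-likelihood per iteration.
#' @return A fitted model of class `hfacs_bn` with elements `structure`,
#'   `cpts`, `loglik` (observed-data log-likelihood of the returned
#'   parameters), `trace` (per-iteration observed-data log-likelihood,
#'   ending at `loglik`), `objective_trace` (the penalized likelihood that
#'   EM with Dirichlet smoothing ascends), `iterations`, `converged`, `n`
#'   (records used) and `settings`.
#' @examples
#' net <- hfacs_structure()
#' truth <- make_ground_truth(generator_config(seed = 1))
#' d <- simulate(truth, nsim = 300, seed = 2)
#' fit <- em_fit(net, d)
#' fit$converged
#' @export
em_fit <- function(structure, data, pseudocount = 1, tol = 1e-6,
                   max_iter = 500L, init = c("uniform", "random"),
                   seed = NULL, max_missing = 8L, verbose = FALSE) {
  init <- match.arg(init)
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  M <- .encode_data(structure, data)
  ex <- .expand_records(structure, M, max_missing)
  if (ex$n_dropped_empty + ex$n_dropped_wide > 0)
    warning(sprintf("dropped %d record(s) with no observed values and %d with > %d missing values",
                    ex$n_dropped_empty, ex$n_dropped_wide, max_missing),
            call. = FALSE)
  n_used <- length(ex$kept)
  if (!n_used) stop("no usable records", call. = FALSE)
  rid <- match(ex$rid, ex$kept)
  L <- .family_indices(structure, ex$A)

  nm <- names(structure$variables)
  card <- .cards(structure)
  nconf <- vapply(nm, .n_parent_configs, integer(1), structure = structure)
  cpts <- if (init == "uniform") uniform_cpts(structure)
          else random_cpts(structure, seed = seed)

  penalty <- function(th) {
    if (pseudocount <= 0) return(0)
    pseudocount * sum(vapply(th, function(m) sum(log(m)), numeric(1)))
  }
  e_step <- function(th) {
    w <- rep(1, nrow(ex$A))
    for (j in seq_along(nm)) w <- w * as.vector(th[[j]])[L[, j]]
    s <- as.vector(rowsum(w, rid))
    if (any(!is.finite(s)) || any(s <= 0))
      stop("a record has probability zero under the current parameters; ",
           "use a positive pseudocount", call. = FALSE)
    list(w = w / s[rid], loglik = sum(log(s)))
  }

  trace <- numeric(0); obj_trace <- numeric(0)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- e_step(cpts)
    trace <- c(trace, es$loglik)
    obj_trace <- c(obj_trace, es$loglik + penalty(cpts))
    if (verbose)
      message(sprintf("iter %3d  loglik %.6f", it, es$loglik))
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) / max(1, abs(trace[it - 1L])) < tol) {
      converged <- TRUE
      break
    }
    for (j in seq_along(nm)) {
      rs <- rowsum(es$w, L[, j])
      cnt <- numeric(nconf[j] * card[j])
      cnt[as.integer(rownames(rs))] <- rs[, 1L]
      cpts[[j]] <- .m_step(matrix(cnt, nconf[j], card[j]), pseudocount,
                           structure$variables[[nm[j]]]$states)
    }
  }
  final <- e_step(cpts)

  out <- hfacs_bn(structure, cpts)
  out$loglik <- final$loglik
  out$trace <- if (converged) trace else c(trace, final$loglik)
  out$objective_trace <- if (converged) obj_trace
                         else c(obj_trace, final$loglik + penalty(cpts))
  out$iterations <- it
  out$converged <- converged
  out$n <- n_used
  out$settings <- list(pseudocount = pseudocount, tol = tol,
                       max_iter = max_iter, init = init, seed = seed,
                       max_missing = max_missing,
                       n_dropped = ex$n_dropped_empty + ex$n_dropped_wide)
  out$call <- match.call()
  out
}

#' Fit the HFACS needlestick-injury network
#'
#' Convenience front end: [em_fit()] on the layered 12-variable HFACS
#' structure.  `data` is a discretized questionnaire dataset as produced by
#' [preprocess_questionnaire()] or [make_study()].
#'
#' @param data Data frame of state labels (may contain `NA`).
#' @param structure Network structure (default [hfacs_structure()]).
#' @param ... Passed to [em_fit()].
#' @return A fitted `hfacs_bn` model.
#' @export
hfacs_bn_fit <- function(data, structure = hfacs_structure(), ...) {
  fit <- em_fit(structure, data, ...)
  fit$call <- match.call()
  fit
}

#' Observed-data log-likelihood of a dataset under a model
#'
#' Missing values are marginalized out exactly (by enumerating each
#' record's completions).
#'
#' @param model An `hfacs_bn` model.
#' @param data Data frame of state labels; `NA` allowed.
#' @param max_missing Maximum missing values per record (as in [em_fit()]).
#' @return Log-likelihood (sum over usable records).
#' @export
bn_loglik <- function(model, data, max_missing = 8L) {
  model <- .as_model(model)
  M <- .encode_data(model$structure, data)
  ex <- .expand_records(model$structure, M, max_missing)
  if (!length(ex$kept)) stop("no usable records", call. = FALSE)
  L <- .family_indices(model$structure, ex$A)
  nm <- names(model$structure$variables)
  w <- rep(1, nrow(ex$A))
  for (j in seq_along(nm)) w <- w * as.vector(model$cpts[[j]])[L[, j]]
  s <- as.vector(rowsum(w, match(ex$rid, ex$kept)))
  if (any(s <= 0)) return(-Inf)
  sum(log(s))
}
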