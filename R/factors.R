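# Internal factor algebra for variable elimination.  A factor is a list
# (vars, card, val) where val is a numeric vector over the cartesian product
# of the variable states in column-major order (first variable fastest).

.f_new <- function(vars, card, val) {
  list(vars = vars, card = as.integer(card), val = as.numeric(val))
}

# Factor for one CPT: vars = (node, parents in reverse canonical order) so
# that the canonical row order (last parent fastest) lines up with
# column-major layout.
.f_from_cpt <- function(structure, cpts, node) {
  pa <- structure$parents[[node]]
  m <- cpts[[node]]
  .f_new(c(node, rev(pa)),
         c(.n_states(structure, node), rev(.cards(structure, pa))),
         as.vector(t(m)))
}

# Value vector of factor f expanded over the joint space of allvars/allcard
# (first variable fastest).
.f_expand <- function(f, allvars, allcard) {
  n <- prod(allcard)
  if (!length(f$vars)) return(rep(f$val, n))
  pos <- match(f$vars, allvars)
  stride_all <- cumprod(c(1, allcard))[seq_along(allcard)]
  stride_f <- cumprod(c(1, f$card))[seq_along(f$card)]
  t0 <- 0:(n - 1)
  idx <- rep(0, n)
  for (j in seq_along(f$vars)) {
    digit <- (t0 %/% stride_all[pos[j]]) %% allcard[pos[j]]
    idx <- idx + digit * stride_f[j]
  }
  f$val[idx + 1]
}

.f_product <- function(f1, f2) {
  allvars <- union(f1$vars, f2$vars)
  allcard <- integer(length(allvars))
  allcard[match(f1$vars, allvars)] <- f1$card
  allcard[match(f2$vars, allvars)] <- f2$card
  .f_new(allvars, allcard,
         .f_expand(f1, allvars, allcard) * .f_expand(f2, allvars, allcard))
}

.f_sumout <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  perm <- c(pos, seq_along(f$vars)[-pos])
  a <- aperm(array(f$val, f$card), perm)
  val <- colSums(matrix(a, nrow = f$card[pos]))
  .f_new(f$vars[-pos], f$card[-pos], val)
}

.f_reduce <- function(f, var, state_idx) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  a <- array(f$val, f$card)
  args <- rep(list(quote(expr = )), length(f$card))
  args[[pos]] <- state_idx
  val <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  .f_new(f$vars[-pos], f$card[-pos], as.vector(val))
}

# Permute a factor's value vector so its variables appear in 'vars' order.
.f_permute <- function(f, vars) {
  perm <- match(vars, f$vars)
  if (length(f$vars) <= 1L || identical(perm, seq_along(f$vars))) {
    f$vars <- vars
    return(f)
  }
  a <- aperm(array(f$val, f$card), perm)
  .f_new(vars, f$card[perm], as.vector(a))
}

# Min-fill elimination order over the factor interaction graph, with
# deterministic tie-break by 'canonical' order.
.min_fill_order <- function(scopes, elim, canonical) {
  elim <- intersect(canonical, elim)
  adj <- stats::setNames(lapply(canonical, function(v) character(0)), canonical)
  for (sc in scopes) for (v in sc) adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  order <- character(0)
  remaining <- elim
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], names(adj))
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L)) for (j in (i + 1L):length(nb))
        if (!(nb[j] %in% adj[[nb[i]]])) cnt <- cnt + 1L
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]   # ties -> earliest in canonical order
    nb <- adj[[v]]
    for (a in nb) adj[[a]] <- union(setdiff(adj[[a]], v), setdiff(nb, a))
    adj[[v]] <- NULL
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}
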