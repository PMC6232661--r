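`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
.assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty string", what), call. = FALSE)
  invisible(x)
}

# Kahn topological sort; errors on cycles.
.topo_sort <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, 0L)
  order <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    v <- ready[[1L]]
    ready <- ready[-1L]
    order <- c(order, v)
    for (w in nodes) {
      if (v %in% parents[[w]]) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) ready <- c(ready, w)
      }
    }
  }
  if (length(order) != length(nodes)) stop("graph contains a cycle", call. = FALSE)
  order
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits.  Used only to
# stamp outputs with a short configuration fingerprint.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor the low 16 bits only (b < 256), keeping everything exact in doubles
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.config_hash <- function(x) .fnv1a(paste(deparse(x), collapse = ""))

# Mixed-radix index of parent configurations, last parent varying fastest.
# idx: integer matrix (n x m) of 1-based state indices in canonical parent
# order; card: parent cardinalities.  Returns 1-based configuration index.
.mixed_radix <- function(idx, card) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  if (length(card) == 0L) return(rep(1L, nrow(idx)))
  mult <- rev(cumprod(rev(c(card[-1L], 1))))
  as.integer(idx %*% mult - sum(mult) + 1)
}
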