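# Shared fixtures, all built in code.

# Three-node chain x -> y -> z (all binary) with hand-set CPTs; small enough
# for hand enumeration.
fix_chain <- function(px = 0.6, a = 0.8, b = 0.3, c = 0.9, d = 0.2) {
  cat3 <- list(bn_variable("x", c("lo", "hi"), measurement = "direct_binary"),
               bn_variable("y", c("lo", "hi"), measurement = "direct_binary"),
               bn_variable("z", c("lo", "hi"), measurement = "direct_binary"))
  st <- bn_structure(cat3, list(y = "x", z = "y"))
  cpts <- list(
    x = matrix(c(px, 1 - px), 1, dimnames = list(NULL, c("lo", "hi"))),
    y = matrix(c(a, 1 - a, b, 1 - b), 2, byrow = TRUE,
               dimnames = list(NULL, c("lo", "hi"))),
    z = matrix(c(c, 1 - c, d, 1 - d), 2, byrow = TRUE,
               dimnames = list(NULL, c("lo", "hi"))))
  hfacs_bn(st, cpts)
}

# Same variables with every edge severed (full independence).
fix_severed <- function(px = 0.6, py = 0.7, pz = 0.25) {
  cat3 <- list(bn_variable("x", c("lo", "hi"), measurement = "direct_binary"),
               bn_variable("y", c("lo", "hi"), measurement = "direct_binary"),
               bn_variable("z", c("lo", "hi"), measurement = "direct_binary"))
  st <- bn_structure(cat3, list())
  mk <- function(p) matrix(c(p, 1 - p), 1, dimnames = list(NULL, c("lo", "hi")))
  hfacs_bn(st, list(x = mk(px), y = mk(py), z = mk(pz)))
}

# Outcome copies a uniform binary predictor deterministically.
fix_copy <- function() {
  cat2 <- list(bn_variable("x", c("a", "b"), measurement = "direct_binary"),
               bn_variable("y", c("a", "b"), measurement = "direct_binary"))
  st <- bn_structure(cat2, list(y = "x"))
  hfacs_bn(st, list(
    x = matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a", "b"))),
    y = matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))))
}

# Seeded random model on the full HFACS structure.
fix_random_hfacs <- function(seed) {
  st <- hfacs_structure()
  hfacs_bn(st, random_cpts(st, seed = seed))
}

# Exhaustive enumeration of full assignments for a small model, as an
# independent oracle (plain loops over expand.grid; no package inference).
oracle_joint_table <- function(model) {
  st <- model$structure
  nm <- names(st$variables)
  states <- lapply(nm, function(v) st$variables[[v]]$states)
  names(states) <- nm
  grid <- expand.grid(states, stringsAsFactors = FALSE)
  grid$prob <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (v in nm) {
      pa <- st$parents[[v]]
      row <- if (length(pa))
        parent_config_index(st, v, as.matrix(grid[i, pa, drop = FALSE]))
      else 1L
      p <- p * model$cpts[[v]][row, grid[i, v]]
    }
    p
  }, numeric(1))
  grid
}
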