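test_that("the variable catalog matches the published HFACS mapping", {
  cat12 <- hfacs_variables()
  expect_length(cat12, 12L)
  ns <- vapply(cat12, function(v) length(v$states), integer(1))
  expect_equal(sum(ns == 3L), 10L)
  expect_equal(sum(ns == 2L), 2L)
  expect_equal(names(which(ns == 2L)), c("safe_procedures", "nsi"))
  expect_equal(cat12$fatigue$states, c("low", "moderate", "high"))
  expect_equal(cat12$working_hours$level, 3L)
  lv <- vapply(cat12, `[[`, integer(1), "level")
  expect_equal(names(which(lv == 4L)),
               c("management_commitment", "staffing", "safe_procedures"))
  expect_equal(names(which(lv == 3L)),
               c("night_shifts", "working_hours", "supervisor_attitude",
                 "safety_training"))
  expect_equal(names(which(lv == 2L)),
               c("fatigue", "teamwork", "physical_environment",
                 "safety_motivation"))
  expect_equal(names(which(lv == 1L)), "nsi")
  expect_equal(cat12$nsi$states, c("yes", "no"))
})

test_that("the layered structure implements both HFACS assumptions", {
  net <- hfacs_structure()
  e <- bn_edges(net)
  expect_equal(nrow(e), 32L)  # 3x4 + 4x4 + 4x1
  lv <- vapply(net$variables, `[[`, integer(1), "level")
  # every edge runs from level L+1 to level L; no within-level edges
  expect_true(all(lv[e$from] == lv[e$to] + 1L))
  # complete bipartite between adjacent levels
  for (v in names(which(lv == 2L)))
    expect_equal(net$parents[[v]], names(which(lv == 3L)))
  expect_equal(net$parents$nsi, names(which(lv == 2L)))
  for (v in names(which(lv == 4L))) expect_length(net$parents[[v]], 0L)
  # no level skipping
  expect_false(any(e$from == "staffing" & e$to == "fatigue"))
  expect_true(any(e$from == "staffing" & e$to == "safety_training"))
  # deterministic construction
  expect_identical(hfacs_structure(), net)
})

test_that("CPT bookkeeping gives the published table sizes", {
  net <- hfacs_structure()
  per <- bn_parameter_count(net, per_node = TRUE)
  expect_equal(max(per), 243L)                   # 3^5 for each L2 node
  expect_equal(bn_parameter_count(net), 1358L)   # 3+3+2 + 4*54 + 4*243 + 162
  expect_equal(unname(per[c("fatigue", "nsi", "working_hours", "staffing")]),
               c(243L, 162L, 54L, 3L))
})

test_that("the generic constructor rejects cycles and unknown parents", {
  cat2 <- list(bn_variable("a", c("s1", "s2"), measurement = "direct_binary"),
               bn_variable("b", c("s1", "s2"), measurement = "direct_binary"))
  expect_error(bn_structure(cat2, list(a = "b", b = "a")), "cycle")
  expect_error(bn_structure(cat2, list(a = "zzz")), "unknown")
  expect_error(bn_structure(cat2, list(a = "a")), "own parent")
  cat_nolevel <- list(bn_variable("a", c("s1", "s2")))
  expect_error(hfacs_structure(cat_nolevel), "level")
})

test_that("parent configurations are numbered last-parent-fastest", {
  net <- hfacs_structure()
  pa <- net$parents$nsi
  first <- vapply(pa, function(p) net$variables[[p]]$states[1], character(1))
  expect_equal(parent_config_index(net, "nsi", first), 1L)
  # advancing the LAST parent by one state advances the index by one
  nxt <- first
  nxt[length(nxt)] <- net$variables[[pa[length(pa)]]]$states[2]
  expect_equal(parent_config_index(net, "nsi", nxt), 2L)
  # advancing the FIRST parent jumps by the product of later cardinalities
  jmp <- first
  jmp[1] <- net$variables[[pa[1]]]$states[2]
  expect_equal(parent_config_index(net, "nsi", jmp), 28L)  # 1 + 3*3*3
  tab <- parent_config_table(net, "nsi")
  expect_equal(nrow(tab), 81L)
  expect_equal(parent_config_index(net, "nsi", tab), 1:81)
})

test_that("joint probability is the chain-rule product of CPT lookups", {
  net <- hfacs_structure()
  u <- uniform_cpts(net)
  a <- vapply(names(net$variables), function(v) net$variables[[v]]$states[1],
              character(1))
  expect_equal(joint_probability(net, u, a), 1 / 236196, tolerance = 1e-12)
  # a zero CPT entry zeroes the joint
  z <- u
  z$nsi[1, ] <- c(0, 1)
  first_l2 <- vapply(net$parents$nsi, function(p) net$variables[[p]]$states[1],
                     character(1))
  a2 <- a; a2[names(first_l2)] <- first_l2; a2["nsi"] <- "yes"
  expect_equal(joint_probability(net, z, a2), 0)
  # seeded random CPTs: agree with an independent lookup-and-multiply oracle
  r <- random_cpts(net, seed = 99)
  set.seed(4)
  a3 <- vapply(names(net$variables), function(v)
    sample(net$variables[[v]]$states, 1), character(1))
  byhand <- 1
  for (v in names(net$variables)) {
    pa <- net$parents[[v]]
    row <- 1L
    if (length(pa)) {
      card <- vapply(pa, function(p) length(net$variables[[p]]$states),
                     integer(1))
      idx <- vapply(pa, function(p) match(a3[[p]], net$variables[[p]]$states),
                    integer(1))
      mult <- rev(cumprod(rev(c(card[-1], 1))))
      row <- as.integer(sum((idx - 1) * mult) + 1)
    }
    byhand <- byhand * r[[v]][row, match(a3[[v]], net$variables[[v]]$states)]
  }
  expect_equal(joint_probability(net, r, a3), unname(byhand),
               tolerance = 1e-15)
  expect_error(joint_probability(net, u, a3[-1]), "missing variable")
})

test_that("the enumerated joint of a small model normalizes to 1", {
  m <- fix_chain()
  tab <- oracle_joint_table(m)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  m2 <- fix_random_hfacs(3)
  # spot-check full-joint normalization through the marginal of a root
  expect_equal(sum(bn_posterior(m2, "staffing")), 1, tolerance = 1e-9)
})

test_that("CPT validation reports exactly the planted violations", {
  net <- hfacs_structure()
  u <- uniform_cpts(net)
  expect_equal(nrow(validate_cpts(net, u)), 0L)
  bad <- u
  bad$fatigue[5, ] <- c(0.3, 0.3, 0.3)       # row sums to 0.9
  v <- validate_cpts(net, bad)
  expect_equal(nrow(v), 1L)
  expect_equal(v$node, "fatigue")
  expect_equal(v$config, 5L)
  expect_equal(v$type, "rowsum")
  bad2 <- u
  bad2$nsi[2, ] <- c(-0.1, 1.1)              # in-range failure (sums to 1)
  v2 <- validate_cpts(net, bad2)
  expect_true(all(v2$type == "range"))
  bad3 <- u
  bad3$staffing <- bad3$staffing[, 1:2]      # size mismatch
  expect_equal(validate_cpts(net, bad3)$type, "size")
  expect_error(hfacs_bn(net, bad), "invalid CPT")
})

test_that("models round-trip through JSON and export valid XMLBIF", {
  m <- fix_random_hfacs(11)
  f <- withr::local_tempfile(fileext = ".json")
  bn_write_json(m, f)
  m2 <- bn_read_json(f)
  expect_identical(names(m2$structure$variables), names(m$structure$variables))
  expect_identical(m2$structure$parents, m$structure$parents)
  for (v in names(m$cpts))
    expect_equal(m2$cpts[[v]], m$cpts[[v]], tolerance = 1e-12)
  x <- withr::local_tempfile(fileext = ".xml")
  bn_write_xmlbif(m, x)
  doc <- xml2::read_xml(x)
  expect_length(xml2::xml_find_all(doc, "//VARIABLE"), 12L)
  defs <- xml2::xml_find_all(doc, "//DEFINITION")
  expect_length(defs, 12L)
  # table lengths match the CPT sizes, child states fastest
  tab <- strsplit(xml2::xml_text(xml2::xml_find_first(defs[[12]], ".//TABLE")),
                  " ")[[1]]
  expect_length(tab, 162L)
})
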