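test_that("the sensitivity index reproduces every published benchmark row", {
  ref <- nsi_reference_sensitivity()
  expect_equal(nrow(ref), 11L)
  got <- round(sensitivity_index(ref$worst_pct, ref$best_pct), 1)
  expect_equal(got, ref$sensitivity_pct)
  expect_equal(sensitivity_index(62.8, 79.5), 26.6, tolerance = 0.05)
  expect_equal(sensitivity_index(71.9, 72.2), 0.4, tolerance = 0.05)
  expect_equal(sensitivity_index(55, 55), 0)
  expect_error(sensitivity_index(0, 10), "undefined")
})

test_that("published best-state posteriors imply the published NSI rates", {
  ref <- nsi_reference_sensitivity()
  expect_equal(100 - ref$best_pct[ref$predictor == "safety_motivation"], 20.5)
  expect_equal(100 - ref$best_pct[ref$predictor == "fatigue"], 21.4)
})

test_that("mutual information matches enumeration and its bounds", {
  # outcome copies a fair coin -> exactly 1 bit, 100% of outcome entropy
  mi <- mutual_information(fix_copy(), "x", "y")
  expect_equal(mi$bits, 1, tolerance = 1e-12)
  expect_equal(mi$percent, 100, tolerance = 1e-9)
  # severed edges -> zero shared information
  mi0 <- mutual_information(fix_severed(), "x", "z")
  expect_equal(mi0$bits, 0, tolerance = 1e-12)
  # chain fixture: agree with brute-force summation over the enumerated joint
  m <- fix_chain(px = 0.35, a = 0.9, b = 0.25, c = 0.7, d = 0.15)
  tab <- oracle_joint_table(m)
  jt <- tapply(tab$prob, list(tab$x, tab$z), sum)
  px <- rowSums(jt); pz <- colSums(jt)
  want <- sum(jt * log2(jt / outer(px, pz)))
  got <- mutual_information(m, "x", "z")
  expect_equal(got$bits, want, tolerance = 1e-12)
  expect_equal(got$outcome_entropy, -sum(pz * log2(pz)), tolerance = 1e-12)
  # bounds: 0 <= MI <= min(H(predictor), H(outcome)) on seeded models
  for (s in 1:4) {
    mr <- fix_random_hfacs(400 + s)
    for (v in c("fatigue", "staffing", "working_hours")) {
      mi <- mutual_information(mr, v, "nsi")
      hx <- {
        p <- as.numeric(bn_posterior(mr, v)); -sum(p[p > 0] * log2(p[p > 0]))
      }
      expect_gte(mi$bits, 0)
      expect_lte(mi$bits, min(hx, mi$outcome_entropy) + 1e-9)
    }
  }
  expect_error(mutual_information(fix_copy(), "y", "y"), "differ")
})

test_that("best/worst scans bracket the baseline and honour determinism", {
  # a state that forces the outcome is the worst state with posterior 0
  m <- fix_chain(px = 0.5, a = 1, b = 0.6, c = 1, d = 0.3)
  # y = lo forces z = lo, i.e. P(z = hi | y = lo) = 0
  bw <- best_worst_scan(m, "y", outcome = "z", favourable = "hi")
  expect_equal(bw$worst_state, "lo")
  expect_equal(bw$worst_pct, 0)
  # independent predictor: best = worst = baseline
  ms <- fix_severed()
  bws <- best_worst_scan(ms, "x", outcome = "z", favourable = "hi")
  base <- 100 * bn_posterior(ms, "z")[["hi"]]
  expect_equal(bws$worst_pct, base, tolerance = 1e-9)
  expect_equal(bws$best_pct, base, tolerance = 1e-9)
  # law of total probability: worst <= baseline <= best on seeded models
  for (s in 1:4) {
    mr <- fix_random_hfacs(500 + s)
    base <- 100 * bn_posterior(mr, "nsi")[["no"]]
    for (v in c("safety_motivation", "management_commitment")) {
      bw <- best_worst_scan(mr, v)
      expect_lte(bw$worst_pct, base + 1e-9)
      expect_gte(bw$best_pct, base - 1e-9)
      # agree with the per-state enumeration oracle
      st1 <- mr$structure$variables[[v]]$states[1]
      expect_equal(bw$posterior_pct[[st1]],
                   100 * enumerate_posterior(
                     mr, "nsi", stats::setNames(list(st1), v))[["no"]],
                   tolerance = 1e-9)
    }
  }
})

test_that("predictor ranking separates strong from null effects", {
  truth <- make_ground_truth(generator_config(seed = 1))
  sens <- sensitivity_analysis(truth)
  expect_equal(nrow(sens), 11L)
  expect_equal(unname(table(sens$group)[unique(sens$group)]),
               c(4L, 4L, 3L), ignore_attr = TRUE)
  # sorted by sensitivity within each level group
  for (g in unique(sens$group))
    expect_false(is.unsorted(rev(sens$sensitivity_pct[sens$group == g])))
  # sensitivity and mutual information agree on the top predictor
  expect_equal(sens$predictor[which.max(sens$sensitivity_pct)],
               sens$predictor[which.max(sens$mi_bits)])
  # zero effect strengths -> outcome independent of every predictor
  null_truth <- make_ground_truth(
    generator_config(seed = 1, effects = list(l3 = 0, l2 = 0, nsi = 0)))
  sens0 <- sensitivity_analysis(null_truth)
  expect_true(all(abs(sens0$sensitivity_pct) < 1e-6))
  expect_true(all(sens0$mi_bits < 1e-12))
})

test_that("interventions compare evidence scenarios against the baseline", {
  truth <- make_ground_truth(generator_config(seed = 1))
  # empty evidence is the baseline
  iv0 <- evaluate_intervention(truth)
  expect_equal(iv0$change_pp, 0)
  expect_equal(iv0$favourable_pct + iv0$nsi_rate_pct, 100)
  # the best simple strategy improves on the baseline
  iv <- evaluate_intervention(truth, list(safety_motivation = "good"))
  expect_gt(iv$favourable_pct, iv$baseline_pct)
  expect_equal(iv$nsi_rate_pct, 100 - iv$favourable_pct)
  # the joint strategy at least matches each of its component strategies
  joint_ev <- list(management_commitment = "good", staffing = "good",
                   supervisor_attitude = "good", working_hours = "normal")
  joint <- evaluate_intervention(truth, joint_ev)
  for (v in names(joint_ev)) {
    single <- evaluate_intervention(truth, joint_ev[v])
    expect_lte(joint$nsi_rate_pct, single$nsi_rate_pct + 1e-9)
  }
  # conditioning on a d-separated variable changes nothing
  ms <- fix_severed()
  ivs <- evaluate_intervention(ms, list(x = "hi"), outcome = "z",
                               favourable = "hi")
  expect_equal(ivs$change_pp, 0, tolerance = 1e-9)
  # do-mode severs the evidence node from its parents
  ivd <- evaluate_intervention(truth, list(safety_motivation = "good"),
                               mode = "do")
  expect_gt(ivd$favourable_pct, iv0$baseline_pct)
  expect_error(evaluate_intervention(truth, list(nsi = "no")), "outcome")
})
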