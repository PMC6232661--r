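test_that("scale scores average the available items", {
  expect_equal(score_scale(c(3, 3, 3, 3)), 3)
  expect_equal(score_scale(c(1, 2, 4, 5)), 3)
  expect_equal(score_scale(c(5, NA, 4, 5)), 14 / 3)
  expect_true(is.na(score_scale(c(NA, NA, NA, NA))))
  # fewer than half the items answered -> missing
  expect_true(is.na(score_scale(c(2, NA, NA, NA))))
  expect_error(score_scale(c(0, 3, 3, 3)), "1..5")
  expect_error(score_scale(c(2.5, 3, 3, 3)), "1..5")
})

test_that("discretization follows the published interval definitions", {
  expect_equal(discretize_value("working_hours", c(30, 44, 45, 55, 56)),
               c("normal", "normal", "high", "high", "very_high"))
  expect_equal(discretize_value("night_shifts", c(0, 8, 9, 11, 12, 16)),
               c("normal", "normal", "high", "high", "very_high", "very_high"))
  # three equal intervals over [1, 5]; left-closed, top interval closed
  expect_equal(discretize_value("fatigue", c(1, 7 / 3 - 1e-9, 7 / 3,
                                             11 / 3 - 1e-9, 11 / 3, 5)),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_equal(discretize_value("safe_procedures", c("yes", NA, "no")),
               c("yes", NA, "no"))
  # re-discretizing a state label is an error, not a no-op
  expect_error(discretize_value("fatigue", "moderate"), "numeric")
  expect_error(discretize_value("fatigue", 5.2), "\\[1, 5\\]")
  expect_error(discretize_value("night_shifts", 3.5), "integer")
  expect_error(discretize_value("safe_procedures", "maybe"), "illegal")
  expect_error(discretize_value("no_such_var", 3), "unknown")
  # total on the legal domain: every Likert score maps to some state
  sc <- seq(1, 5, by = 0.01)
  expect_false(anyNA(discretize_value("teamwork", sc)))
})

test_that("Cronbach alpha matches closed forms and simulation", {
  # identical columns -> alpha = 1
  x <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(x), 1)
  # two items with unit sample variances and covariance 1/2:
  # alpha = 2 * (1 - 2/3) = 2/3, on an exactly constructed fixture
  z1 <- c(-1, 0, 1)
  w <- c(1, -2, 1) / sqrt(3)             # unit variance, orthogonal to z1
  z2 <- 0.5 * z1 + sqrt(3) / 2 * w
  expect_equal(stats::var(z1), 1)
  expect_equal(stats::var(z2), 1)
  expect_equal(stats::cov(z1, z2), 0.5)
  expect_equal(cronbach_alpha(cbind(z1, z2)), 2 / 3, tolerance = 1e-12)
  # independent items -> alpha near 0
  set.seed(1)
  r <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(r)), 0.1)
  # degenerate inputs signal explicitly
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), ncol = 1)), "2 items")
  # listwise deletion: an NA row is ignored, not propagated
  x2 <- rbind(x, c(NA, 1, 1))
  expect_equal(cronbach_alpha(x2), 1)
})

test_that("straight-lining is flagged by zero response variance", {
  cfg <- generator_config(seed = 5, n = 10, missing_rate = 0,
                          straightliner_frac = 0.2)
  resp <- sample_respondents(make_ground_truth(cfg), cfg)
  flags <- detect_straightlining(resp$records)
  expect_equal(sum(flags), 2L)
  expect_equal(which(flags), resp$straightliners)
  # a varied respondent is never flagged
  expect_false(any(flags[setdiff(1:10, resp$straightliners)]))
})

test_that("preprocessing reproduces the study bookkeeping on synthetic data", {
  cfg <- generator_config(seed = 21)          # n = 408, 14 straight-liners
  resp <- sample_respondents(make_ground_truth(cfg), cfg)
  prep <- preprocess_questionnaire(resp$records)
  expect_equal(prep$report$received, 408L)
  expect_equal(prep$report$discarded, 14L)
  expect_equal(prep$report$retained, 394L)
  expect_equal(nrow(prep$data), 394L)
  # every non-missing value is a legal state of its variable
  cat12 <- hfacs_variables()
  for (v in names(cat12)) {
    vals <- prep$data[[v]]
    expect_true(all(is.na(vals) | vals %in% cat12[[v]]$states), label = v)
  }
  # records with a missing NSI answer are retained with a missing outcome
  raw_kept <- resp$records[prep$kept, ]
  miss_nsi <- which(is.na(raw_kept$nsi))
  expect_gt(length(miss_nsi), 0L)
  expect_true(all(is.na(prep$data$nsi[miss_nsi])))
  # filtering never alters retained records: recompute one scale by hand
  i <- which(!is.na(raw_kept$fatigue_i1))[1]
  sc <- score_scale(as.numeric(raw_kept[i, paste0("fatigue_i", 1:4)]))
  expect_equal(prep$data$fatigue[i], discretize_value("fatigue", sc))
})

test_that("empty input yields an empty dataset with a warning", {
  cfg <- generator_config(seed = 1, n = 2)
  resp <- sample_respondents(make_ground_truth(cfg), cfg)
  expect_warning(prep <- preprocess_questionnaire(resp$records[0, ]), "empty")
  expect_equal(nrow(prep$data), 0L)
  expect_equal(prep$report$received, 0L)
})

test_that("the train/test split follows the study sizes and scales down", {
  d <- data.frame(nsi = rep(c("yes", "no"), 250))  # 500 records
  s <- split_train_test(d, seed = 3)
  expect_equal(unname(s$sizes), c(343L, 50L, 107L))
  expect_equal(nrow(s$train), 343L)
  expect_equal(nrow(s$test), 50L)
  # below the study scale the 343:50 proportion is kept
  s2 <- split_train_test(d[1:100, , drop = FALSE], seed = 3)
  expect_equal(unname(s2$sizes[1:2]), c(87L, 13L))
  # deterministic under a seed, disjoint, and exhaustive
  s3 <- split_train_test(d, seed = 3)
  expect_identical(s$train, s3$train)
  expect_equal(sort(c(rownames(s$train), rownames(s$test), rownames(s$unused))),
               sort(rownames(d)))
  expect_error(split_train_test(d[1:10, , drop = FALSE], seed = 1,
                                train_size = 9, test_size = 5), "larger")
})

test_that("discrete CSV round-trips through the provenance-stamped writer", {
  d <- data.frame(nsi = c("yes", NA, "no"), fatigue = c("low", "high", NA),
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_discrete_csv(d, f, provenance = list(seed = 1, config = "abc"))
  expect_match(readLines(f, n = 1), "^# provenance: seed=1")
  back <- read_questionnaire_csv(f)
  expect_equal(back, d)
})
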