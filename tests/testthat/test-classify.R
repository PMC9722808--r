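sparse <- task_config("sparse")
dense <- task_config("dense")
tr <- function(on, obs) list(on_set = as.integer(on), lights_on = obs)

test_that("eligibility keeps trials with at least four candidates in contention", {
  s1 <- list(tr(1:3, TRUE), tr(1, FALSE), tr(2, TRUE))  # beliefs 6, 3, 2
  expect_equal(eligible_trials(s1, sparse), 1L)
  d1 <- list(tr(1, TRUE), tr(2, TRUE), tr(3, TRUE), tr(4, FALSE))  # 6,5,4,3
  expect_equal(eligible_trials(d1, dense), 1:3)
  d2 <- list(tr(c(1, 2), TRUE), tr(c(3, 4), TRUE))  # beliefs stay at 6
  expect_equal(eligible_trials(d2, dense), 1:2)
})

test_that("sessions are labeled by the on-set sizes of eligible trials", {
  ones <- list(tr(1, TRUE), tr(2, TRUE), tr(3, TRUE))
  expect_equal(classify_strategy(ones, dense)$label, "test_one")
  multi <- list(tr(c(1, 2, 3), TRUE), tr(c(4, 5), TRUE))
  expect_equal(classify_strategy(multi, dense)$label, "test_multiple")
  mixed <- list(tr(c(1, 2, 3), TRUE), tr(4, TRUE))
  expect_equal(classify_strategy(mixed, dense)$label, "other")
  none <- classify_strategy(list(), sparse)
  expect_equal(none$label, "unclassifiable")
  expect_equal(none$n_eligible, 0L)
  expect_true(is.na(none$info_optimal))
})

test_that("the label never depends on ineligible trials", {
  # trial 1 collapses the sparse belief to {1,2,3}; trial 2 is ineligible
  variants <- list(tr(2, TRUE), tr(1, FALSE), tr(c(1, 2), TRUE),
                   tr(c(2, 3), TRUE))
  labels <- vapply(variants, function(v)
    classify_strategy(list(tr(1:3, TRUE), v), sparse)$label, character(1))
  expect_true(all(labels == "test_multiple"))
})

test_that("the rule criterion brackets the ideal search patterns", {
  # sparse: first test 2-4 switches, then half of those in contention
  expect_true(is_information_optimal(list(tr(1:3, TRUE), tr(1, TRUE)),
                                     sparse, mode = "rule"))
  expect_false(is_information_optimal(list(tr(1:5, TRUE)), sparse,
                                      mode = "rule"))
  expect_true(is_information_optimal(list(tr(1:2, FALSE), tr(c(3, 4), FALSE)),
                                     sparse, mode = "rule"))
  # dense: a new single switch every time
  expect_true(is_information_optimal(list(tr(1, TRUE), tr(2, TRUE)),
                                     dense, mode = "rule"))
  expect_false(is_information_optimal(list(tr(2, TRUE), tr(2, TRUE)),
                                      dense, mode = "rule"))
  expect_false(is_information_optimal(list(tr(c(1, 2), TRUE), tr(3, TRUE)),
                                      dense, mode = "rule"))
})

test_that("rule and strict-EIG criteria diverge on 2- and 4-switch openings", {
  # a 2-switch first test from six candidates passes the rule but is not an
  # EIG maximizer (0.918 < 1 bit)
  s <- list(tr(1:2, FALSE), tr(c(3, 4), FALSE))
  expect_true(is_information_optimal(s, sparse, mode = "rule"))
  expect_false(is_information_optimal(s, sparse, mode = "strict_eig"))
  expect_equal(expected_information_gain(1:6, 1:2, sparse),
               log2(6) - (2 / 6) * 1 - (4 / 6) * 2, tolerance = 1e-9)
  # the 3-switch opening satisfies both
  s3 <- list(tr(1:3, FALSE))
  expect_true(is_information_optimal(s3, sparse, mode = "rule"))
  expect_true(is_information_optimal(s3, sparse, mode = "strict_eig"))
})

test_that("first-intervention table counts one- vs multi-switch openers", {
  p1 <- fixture_participant("a", sparse, 2, list(tr(2, TRUE)), 2,
                            age_group = "younger")
  p2 <- fixture_participant("b", sparse, 5, list(tr(1:3, FALSE), tr(5, TRUE)),
                            5, age_group = "younger")
  fi <- first_intervention_summary(fixture_cohort(list(p1, p2)))
  expect_equal(fi$n, 2)
  expect_equal(fi$test_one, 1)
  expect_equal(fi$test_multiple, 1)
  expect_equal(fi$test_one_pct, 50)
})

test_that("a cohort planted with pure strategies recovers its counts exactly", {
  cells <- data.frame(
    age_group = c("younger", "older"), condition = c("sparse", "dense"),
    n = c(40L, 40L), p_test_one = c(0.5, 0.25), p_split_half = c(0.5, 0.75),
    p_other = 0, inference_noise = 0, stringsAsFactors = FALSE)
  co <- generate_cohort(cohort_spec(cells, seed = 8))
  planted <- vapply(co, `[[`, character(1), "strategy")
  fi <- first_intervention_summary(co)
  by_cell <- split(planted, vapply(co, `[[`, character(1), "age_group"))
  expect_equal(fi$test_one[fi$age_group == "younger"],
               sum(by_cell$younger == "test_one"))
  expect_equal(fi$test_one[fi$age_group == "older"],
               sum(by_cell$older == "test_one"))
})

test_that("anomaly flags mark early stops and uninformative tests", {
  config <- sparse
  # certainty reached, then one more pointless test
  trials <- list(tr(1:3, TRUE), tr(c(1, 2), TRUE), tr(1, TRUE), tr(1, TRUE))
  g <- data.frame(guess_index = 1L, guessed_switch = 1L,
                  verified_correct = TRUE)
  f <- flag_session_anomalies(trials, g, config)
  expect_false(f$early_stop)
  expect_true(f$unnecessary_tests)
  # guess with two candidates left
  trials2 <- list(tr(1:3, TRUE), tr(1, FALSE))
  f2 <- flag_session_anomalies(trials2, g, config)
  expect_true(f2$early_stop)
  expect_false(f2$unnecessary_tests)
  # a greedy session run to certainty then a correct guess raises no flags
  sess <- run_policy(policy_spec("greedy_eig", seed = 2), config, 4)
  f3 <- flag_session_anomalies(sess, data.frame(
    guess_index = 1L, guessed_switch = 4L, verified_correct = TRUE), config)
  expect_false(f3$early_stop)
  expect_false(f3$unnecessary_tests)
})
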