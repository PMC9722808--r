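test_that("cohort generation is deterministic under its seed", {
  a <- generate_cohort(cohort_spec(seed = 12))
  b <- generate_cohort(cohort_spec(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cohort_spec(seed = 13))))
  # byte-identical logs
  d <- withr::local_tempdir()
  write_trial_log(a, file.path(d, "a.csv"))
  write_trial_log(b, file.path(d, "b.csv"))
  expect_identical(readLines(file.path(d, "a.csv")),
                   readLines(file.path(d, "b.csv")))
})

test_that("every generated record is consistent with the task model", {
  co <- generate_cohort(cohort_spec(seed = 2))
  for (p in co) {
    config <- task_config(p$condition)
    expect_lte(length(p$trials), config$n_tokens)
    for (tr in p$trials)
      expect_equal(simulate_outcome(config, p$target, tr$on_set),
                   tr$lights_on)
    expect_true(p$guesses$verified_correct[nrow(p$guesses)])
    expect_equal(p$guesses$guessed_switch[nrow(p$guesses)], p$target)
    expect_equal(p$payout,
                 realized_payout(length(p$trials),
                                 p$guesses$verified_correct[1], payout_rule()))
  }
})

test_that("trial logs round-trip through CSV", {
  co <- generate_cohort(cohort_spec(seed = 4))
  d <- withr::local_tempdir()
  path <- file.path(d, "trials.csv")
  write_trial_log(co, path)
  co2 <- read_trial_log(path)
  expect_equal(length(co2), length(co))
  for (i in seq_along(co)) {
    for (field in c("id", "age_group", "condition", "target", "trials",
                    "payout"))
      expect_equal(co2[[i]][[field]], co[[i]][[field]])
    expect_equal(co2[[i]]$guesses, co[[i]]$guesses, ignore_attr = TRUE)
    expect_true(is.na(co2[[i]]$strategy))  # planted strategy not written
  }
  # with the optional strategy column the round trip is fully lossless
  write_trial_log(co, file.path(d, "s.csv"), include_strategy = TRUE)
  co3 <- read_trial_log(file.path(d, "s.csv"))
  expect_equal(vapply(co3, `[[`, character(1), "strategy"),
               vapply(co, `[[`, character(1), "strategy"))
})

test_that("malformed trial logs raise parse errors naming the problem", {
  co <- generate_cohort(cohort_spec(seed = 4))
  d <- withr::local_tempdir()
  path <- file.path(d, "trials.csv")
  write_trial_log(co, path)
  expect_error(read_trial_log(path, n_switches = 7), "expected 7 switch")
  raw <- read.csv(path)
  raw$lights_on <- NULL
  write.csv(raw, file.path(d, "noout.csv"), row.names = FALSE)
  file.copy(sub("\\.csv$", "_guesses.csv", path),
            file.path(d, "noout_guesses.csv"))
  expect_error(read_trial_log(file.path(d, "noout.csv")), "lights_on")
  raw2 <- read.csv(path)
  raw2$s3[5] <- 2L
  write.csv(raw2, file.path(d, "bad.csv"), row.names = FALSE)
  file.copy(sub("\\.csv$", "_guesses.csv", path),
            file.path(d, "bad_guesses.csv"))
  expect_error(read_trial_log(file.path(d, "bad.csv")), "line 6.*s3")
})

test_that("noise-free planted mixtures are recovered by classification", {
  cells <- data.frame(
    age_group = c("younger", "older"), condition = c("sparse", "dense"),
    n = 160L, p_test_one = 0.5, p_split_half = 0.5, p_other = 0,
    inference_noise = 0, stringsAsFactors = FALSE)
  co <- generate_cohort(cohort_spec(cells, seed = 31))
  planted <- vapply(co, `[[`, character(1), "strategy")
  labels <- vapply(co, function(p)
    classify_strategy(p$trials, task_config(p$condition))$label, character(1))
  # 100% agreement between planted and recovered strategies
  expect_true(all(labels[planted == "test_one"] == "test_one"))
  expect_true(all(labels[planted == "split_half"] == "test_multiple"))
  # and the observed mixture sits inside the exact binomial 99% band
  n_t1 <- sum(labels == "test_one")
  band <- qbinom(c(0.005, 0.995), length(co), 0.5)
  expect_gte(n_t1, band[1])
  expect_lte(n_t1, band[2])
  # noise-free simulants answer correctly whenever certainty is reachable:
  # always in sparse, and for test-one simulants in dense (split-half tests
  # are uninformative there, so those simulants can only guess)
  correct1 <- vapply(co, function(p) p$guesses$verified_correct[1], logical(1))
  reachable <- vapply(co, `[[`, character(1), "condition") == "sparse" |
    planted == "test_one"
  expect_true(all(correct1[reachable]))
})

test_that("strategy switchers with enough eligible trials classify as other", {
  cells <- data.frame(
    age_group = "younger", condition = "dense", n = 60L, p_test_one = 0,
    p_split_half = 0, p_other = 1, inference_noise = 0,
    stringsAsFactors = FALSE)
  co <- generate_cohort(cohort_spec(cells, seed = 6))
  res <- vapply(co, function(p)
    classify_strategy(p$trials, task_config(p$condition)), vector("list", 3))
  multi_eligible <- unlist(res["n_eligible", ]) >= 2
  expect_gt(mean(multi_eligible), 0.5)
  expect_true(all(unlist(res["label", multi_eligible]) == "other"))
})

test_that("inference noise lowers the accuracy of test-multiple simulants", {
  mk <- function(noise, seed) {
    cells <- data.frame(
      age_group = "older", condition = "sparse", n = 120L, p_test_one = 0,
      p_split_half = 1, p_other = 0, inference_noise = noise,
      stringsAsFactors = FALSE)
    co <- generate_cohort(cohort_spec(cells, seed = seed))
    mean(vapply(co, function(p) p$guesses$verified_correct[1], logical(1)))
  }
  expect_equal(mk(0, 9), 1.0)
  expect_lt(mk(0.8, 9), mk(0.2, 9))
  expect_lt(mk(0.8, 9), 1.0)
})
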