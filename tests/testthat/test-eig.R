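sparse <- task_config("sparse")
dense <- task_config("dense")

test_that("EIG reproduces the closed-form values for the six-switch box", {
  expect_equal(expected_information_gain(1:6, 1:3, sparse), 1.0,
               tolerance = 1e-9)
  expect_equal(expected_information_gain(1:6, 1, sparse),
               log2(6) - (5 / 6) * log2(5), tolerance = 1e-9)  # 0.650 bits
  expect_equal(expected_information_gain(1:6, c(1, 2), dense), 0)
  expect_equal(expected_information_gain(4L, c(1, 4), sparse), 0)
  expect_equal(expected_information_gain(4L, c(1, 4), dense), 0)
})

test_that("enumeration covers every nonempty on-set with exact values", {
  vals <- enumerate_intervention_values(1:6, sparse)
  expect_equal(nrow(vals), 63)
  expect_equal(max(vals$eig), 1.0, tolerance = 1e-9)
  dvals <- enumerate_intervention_values(1:6, dense)
  pos <- dvals[dvals$eig > 1e-12, ]
  expect_equal(nrow(pos), 6)
  expect_true(all(pos$size == 1))
  expect_error(
    enumerate_intervention_values(1:2, task_config("sparse", n_switches = 17)),
    "enumeration")
})

test_that("closed-form best EIG equals brute-force maximum (n <= 8)", {
  for (cond in c("sparse", "dense")) {
    for (n in 2:6) {
      config <- task_config(cond, n_switches = n)
      for (mask in seq_len(2^n - 1)) {
        cand <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
        expect_equal(best_intervention_value(cand, config),
                     max(enumerate_intervention_values(cand, config)$eig),
                     tolerance = 1e-9)
      }
    }
    set.seed(8)
    for (n in 7:8) {
      config <- task_config(cond, n_switches = n)
      for (k in 1:n) for (r in 1:2) {
        cand <- sort(sample.int(n, k))
        expect_equal(best_intervention_value(cand, config),
                     oracle_best(cond, cand, n), tolerance = 1e-9)
      }
    }
  }
})

test_that("EIG agrees with the independent outcome-enumeration oracle", {
  set.seed(21)
  for (rep in 1:200) {
    cond <- sample(c("sparse", "dense"), 1)
    n <- sample(3:8, 1)
    config <- task_config(cond, n_switches = n)
    cand <- sort(sample.int(n, sample.int(n, 1)))
    on_set <- which(runif(n) < 0.5)
    expect_equal(expected_information_gain(cand, on_set, config),
                 oracle_eig(cond, cand, on_set), tolerance = 1e-12)
  }
})

test_that("in sparse the EIG maximizers split the candidates evenly", {
  n <- 8L
  config <- task_config("sparse", n_switches = n)
  sets <- lapply(seq_len(2^n - 1), function(m)
    which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L))
  set.seed(5)
  for (m in 2:8) {
    cand <- sort(sample.int(n, m))
    eig <- vapply(sets, function(s)
      expected_information_gain(cand, s, config), numeric(1))
    argmax <- which(eig >= max(eig) - 1e-12)
    halves <- c(floor(m / 2), ceiling(m / 2))
    even_split <- which(vapply(sets, function(s)
      length(intersect(s, cand)) %in% halves, logical(1)))
    expect_setequal(argmax, even_split)
  }
})

test_that("in dense only untried single candidates are informative", {
  n <- 6L
  config <- task_config("dense", n_switches = n)
  sets <- lapply(seq_len(2^n - 1), function(m)
    which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L))
  for (m in 3:6) {
    cand <- seq_len(m)
    eig <- vapply(sets, function(s)
      expected_information_gain(cand, s, config), numeric(1))
    informative <- vapply(sets, function(s)
      length(s) == 1L && s %in% cand, logical(1))
    expect_identical(eig > 1e-12, informative)
  }
})

test_that("EIG and efficiency respect their bounds", {
  set.seed(31)
  for (rep in 1:150) {
    cond <- sample(c("sparse", "dense"), 1)
    config <- task_config(cond)
    cand <- sort(sample.int(6, sample.int(6, 1)))
    on_set <- which(runif(6) < 0.5)
    eig <- expected_information_gain(cand, on_set, config)
    expect_gte(eig, 0)
    expect_lte(eig, belief_entropy(cand) + 1e-12)
    eff <- efficiency_of_choice(cand, on_set, config)
    if (!is.na(eff)) {
      expect_gte(eff, 0)
      expect_lte(eff, 1 + 1e-12)
    } else {
      expect_equal(best_intervention_value(cand, config), 0)
    }
  }
})

test_that("per-trial efficiency tracks the true posterior", {
  expect_equal(efficiency_of_choice(1:6, 1, sparse),
               (log2(6) - (5 / 6) * log2(5)) / 1.0, tolerance = 1e-9)
  expect_equal(efficiency_of_choice(1:6, 1:3, sparse), 1.0)
  expect_true(is.na(efficiency_of_choice(6L, c(1, 2), dense)))

  one_trial <- list(list(on_set = 1L, lights_on = FALSE))
  eff <- participant_efficiency(one_trial, sparse)
  expect_equal(eff$mean, log2(6) - (5 / 6) * log2(5), tolerance = 1e-9)
  expect_equal(eff$n_defined, 1L)

  optimal <- list(list(on_set = 1:3, lights_on = FALSE),
                  list(on_set = 4L, lights_on = FALSE))
  expect_equal(participant_efficiency(optimal, sparse)$mean, 1.0)

  # after the target is certain nothing can be learned: undefined trials only
  solved <- list(list(on_set = 5L, lights_on = TRUE),
                 list(on_set = 5L, lights_on = TRUE))
  eff2 <- participant_efficiency(solved, sparse)
  expect_equal(eff2$n_defined, 1L)
  expect_true(is.na(eff2$per_trial[2]))
})
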