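#' Trials eligible for strategy classification
#'
#' Classification conditions on the trials where the choice between testing
#' one and testing several switches is diagnostic: those with at least
#' `min_contention` candidates still in contention before the test.
#'
#' @param trials List of trials (`on_set`, `lights_on`) in order.
#' @param config A [task_config()].
#' @param min_contention Minimum pre-trial candidate-set size (default 4).
#' @return Integer vector of eligible trial indices (possibly empty).
#' @export
eligible_trials <- function(trials, config, min_contention = 4L) {
  beliefs <- candidates_in_contention(trials, config)
  which(lengths(beliefs) >= min_contention)
}

#' Classify a session's intervention strategy
#'
#' `test_one` if every eligible trial turns on exactly one switch,
#' `test_multiple` if every eligible trial turns on more than one,
#' `other` if the session mixes the two, and `unclassifiable` if no trial is
#' eligible (such sessions are excluded from strategy tables).
#'
#' @inheritParams eligible_trials
#' @param mode Information-optimality mode passed to
#'   [is_information_optimal()].
#' @return A list with `label`, `info_optimal` (logical, `NA` when
#'   unclassifiable) and `n_eligible`.
#' @export
classify_strategy <- function(trials, config, min_contention = 4L,
                              mode = c("rule", "strict_eig")) {
  mode <- match.arg(mode)
  elig <- eligible_trials(trials, config, min_contention)
  if (length(elig) == 0L)
    return(list(label = "unclassifiable", info_optimal = NA,
                n_eligible = 0L))
  sizes <- vapply(trials[elig], function(tr) length(tr$on_set), integer(1))
  label <- if (all(sizes == 1L)) "test_one"
           else if (all(sizes > 1L)) "test_multiple"
           else "other"
  list(label = label,
       info_optimal = is_information_optimal(trials, config, mode,
                                             min_contention),
       n_eligible = length(elig))
}

#' Was a session information-optimal over its eligible trials?
#'
#' Two criteria are offered. `"rule"` (default, used for strategy-table
#' bracket counts) is the heuristic ideal: in the sparse condition the first
#' eligible test turns on 2--4 switches and each later eligible test turns on
#' half of the switches still in contention (rounded either way, drawn from
#' the candidates); in the dense condition every eligible test turns on a
#' single previously untested switch. `"strict_eig"` demands that every
#' eligible test attain the maximum expected information gain. The two
#' deliberately differ in the sparse condition: a 2- or 4-switch first test
#' from six candidates passes the rule while yielding 0.918 of the optimal
#' 1 bit.
#'
#' @inheritParams eligible_trials
#' @param mode `"rule"` or `"strict_eig"`.
#' @return Logical; `NA` when no trial is eligible.
#' @export
is_information_optimal <- function(trials, config,
                                   mode = c("rule", "strict_eig"),
                                   min_contention = 4L) {
  mode <- match.arg(mode)
  beliefs <- candidates_in_contention(trials, config)
  elig <- which(lengths(beliefs) >= min_contention)
  if (length(elig) == 0L) return(NA)
  if (mode == "strict_eig") {
    return(all(vapply(elig, function(i) {
      eig <- expected_information_gain(beliefs[[i]], trials[[i]]$on_set, config)
      eig >= best_intervention_value(beliefs[[i]], config) - 1e-9
    }, logical(1))))
  }
  if (config$condition == "sparse") {
    for (j in seq_along(elig)) {
      i <- elig[j]
      on_set <- trials[[i]]$on_set
      if (j == 1L) {
        if (length(on_set) < 2L || length(on_set) > 4L) return(FALSE)
      } else {
        cset <- beliefs[[i]]
        m <- length(cset)
        if (!all(on_set %in% cset)) return(FALSE)
        if (!(length(on_set) %in% c(floor(m / 2), ceiling(m / 2))))
          return(FALSE)
      }
    }
    TRUE
  } else {
    for (i in elig) {
      on_set <- trials[[i]]$on_set
      if (length(on_set) != 1L) return(FALSE)
      earlier <- unlist(lapply(trials[seq_len(i - 1L)], `[[`, "on_set"))
      if (on_set %in% earlier) return(FALSE)
    }
    TRUE
  }
}

#' First-intervention counts by age group and condition
#'
#' Cross-tabulates whether each participant's very first paid test turned on
#' one switch or several, by age group and condition.
#'
#' @param cohort A list of participant records (each with at least one trial).
#' @return A data frame with columns `age_group`, `condition`, `n`,
#'   `test_one`, `test_multiple`, `test_one_pct`, `test_multiple_pct`.
#' @export
first_intervention_summary <- function(cohort) {
  stopifnot(length(cohort) > 0L)
  rows <- lapply(cohort, function(p) {
    if (length(p$trials) == 0L)
      stop(sprintf("participant %s has no trials", p$id), call. = FALSE)
    data.frame(age_group = p$age_group, condition = p$condition,
               one = length(p$trials[[1]]$on_set) == 1L,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  agg <- aggregate(list(test_one = as.numeric(d$one), n = rep(1, nrow(d))),
                   by = list(age_group = d$age_group, condition = d$condition),
                   FUN = sum)
  agg$test_multiple <- agg$n - agg$test_one
  agg$test_one_pct <- 100 * agg$test_one / agg$n
  agg$test_multiple_pct <- 100 * agg$test_multiple / agg$n
  agg[order(agg$age_group, agg$condition),
      c("age_group", "condition", "n", "test_one", "test_multiple",
        "test_one_pct", "test_multiple_pct")]
}

#' Flag early stopping and unnecessary tests in a session
#'
#' Documented approximations: `early_stop` is `TRUE` when the first guess was
#' made while two or more candidates were still in contention;
#' `unnecessary_tests` is `TRUE` when any paid test could learn nothing
#' (best available EIG 0, e.g. testing after the target was already certain)
#' or learned nothing by choice (chosen EIG 0, e.g. an empty or vacuous
#' on-set).
#'
#' @param trials List of trials in order.
#' @param guesses Data frame of guesses (may have zero rows).
#' @param config A [task_config()].
#' @return A list with logical `early_stop` and `unnecessary_tests`.
#' @export
flag_session_anomalies <- function(trials, guesses, config) {
  beliefs <- candidates_in_contention(trials, config)
  final <- final_belief(trials, config)
  early_stop <- nrow(guesses) > 0L && length(final) >= 2L
  unnecessary <- any(vapply(seq_along(trials), function(i) {
    best <- best_intervention_value(beliefs[[i]], config)
    best <= 0 ||
      expected_information_gain(beliefs[[i]], trials[[i]]$on_set, config) <= 0
  }, logical(1)))
  list(early_stop = early_stop, unnecessary_tests = unnecessary)
}
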