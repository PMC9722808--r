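#' Analyze a cohort of switch-box sessions
#'
#' Runs the full analysis pipeline on a cohort (real or synthetic): belief
#' tracking, strategy classification with information-optimality brackets,
#' first-intervention counts, per-participant intervention efficiency, the
#' simulated baseline learners (matched random, pure test-one, pure
#' split-half), and guess-accuracy contingency tables with two-sided Fisher
#' exact p-values for participants classified as test-multiple.
#'
#' @param cohort A `switchbox_cohort` (see [generate_cohort()] /
#'   [read_trial_log()]).
#' @param seed Integer seed driving the simulated baselines and bootstrap.
#' @param min_contention Eligibility threshold for classification (default 4
#'   candidates still in contention).
#' @param mode Information-optimality criterion, see
#'   [is_information_optimal()].
#' @param conf_level Level of the bootstrap confidence intervals.
#' @param n_boot Bootstrap resamples for group-mean intervals.
#' @return An object of class `switchbox_analysis`.
#' @export
analyze_cohort <- function(cohort, seed = 1L, min_contention = 4L,
                           mode = c("rule", "strict_eig"), conf_level = 0.95,
                           n_boot = 2000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "switchbox_cohort") || is.list(cohort))
  base <- cohort_base_config(cohort)
  cfg_of <- function(p) task_config(p$condition, base$n_switches,
                                    base$n_tokens, base$token_value)

  participants <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    config <- cfg_of(p)
    cls <- tryCatch(
      classify_strategy(p$trials, config, min_contention, mode),
      error = function(e) stop(sprintf("participant %s: %s", p$id,
                                       conditionMessage(e)), call. = FALSE))
    eff <- participant_efficiency(p$trials, config)
    flags <- flag_session_anomalies(p$trials, p$guesses, config)
    data.frame(
      id = p$id, age_group = p$age_group, condition = p$condition,
      n_trials = length(p$trials), strategy = cls$label,
      info_optimal = isTRUE(cls$info_optimal),
      n_eligible = cls$n_eligible,
      correct = nrow(p$guesses) > 0L && p$guesses$verified_correct[1],
      payout = p$payout, efficiency = eff$mean,
      early_stop = flags$early_stop,
      unnecessary_tests = flags$unnecessary_tests,
      stringsAsFactors = FALSE)
  }))

  # strategy proportions with information-optimal bracket counts (Fig-2 style)
  classified <- participants[participants$strategy != "unclassifiable", ]
  strategy_table <- do.call(rbind, lapply(
    split(classified, list(classified$age_group, classified$condition),
          drop = TRUE),
    function(g) do.call(rbind, lapply(c("test_one", "test_multiple", "other"),
      function(lab) {
        sub <- g[g$strategy == lab, ]
        data.frame(age_group = g$age_group[1], condition = g$condition[1],
                   strategy = lab, count = nrow(sub),
                   proportion = nrow(sub) / nrow(g),
                   info_optimal = sum(sub$info_optimal),
                   stringsAsFactors = FALSE)
      }))))
  rownames(strategy_table) <- NULL

  # baseline learners, one simulant per participant, seeded streams
  sim_policy_eff <- function(kind) {
    vapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]
      config <- cfg_of(p)
      pol <- policy_spec(kind, seed = derive_seed(seed, i * 7L +
                                                    match(kind, c("test_one", "split_half"))))
      trials <- run_policy(pol, config, p$target)
      participant_efficiency(trials, config)$mean
    }, numeric(1))
  }
  rnd <- matched_random_cohort(cohort, seed = derive_seed(seed, 999L))
  baselines <- data.frame(
    id = participants$id, age_group = participants$age_group,
    condition = participants$condition,
    participants = participants$efficiency,
    random = vapply(rnd, function(p)
      participant_efficiency(p$trials, cfg_of(p))$mean, numeric(1)),
    test_one = sim_policy_eff("test_one"),
    split_half = sim_policy_eff("split_half"),
    stringsAsFactors = FALSE)

  group_means <- do.call(rbind, lapply(
    split(baselines, list(baselines$age_group, baselines$condition),
          drop = TRUE),
    function(g) do.call(rbind, lapply(
      c("participants", "random", "test_one", "split_half"), function(col) {
        v <- g[[col]][!is.na(g[[col]])]
        ci <- if (length(v)) bootstrap_mean_ci(v, conf_level, n_boot,
                                               derive_seed(seed, 17L))
              else c(NA_real_, NA_real_)
        data.frame(age_group = g$age_group[1], condition = g$condition[1],
                   learner = col, n = length(v),
                   mean_efficiency = if (length(v)) mean(v) else NA_real_,
                   ci_lower = ci[1], ci_upper = ci[2],
                   stringsAsFactors = FALSE)
      }))))
  rownames(group_means) <- NULL

  # guess accuracy of test-multiple users, younger vs older, per condition
  contingency <- do.call(rbind, lapply(c("sparse", "dense", "all"),
    function(cond) {
      sub <- classified[classified$strategy == "test_multiple", ]
      if (cond != "all") sub <- sub[sub$condition == cond, ]
      if (nrow(sub) == 0L || length(unique(sub$age_group)) < 2L)
        return(data.frame(condition = cond, younger_correct = NA, younger_n = NA,
                          older_correct = NA, older_n = NA,
                          fisher_p = NA_real_, stringsAsFactors = FALSE))
      tab <- proportion_table(factor(sub$age_group,
                                     levels = c("older", "younger")),
                              sub$correct)
      data.frame(condition = cond,
                 younger_correct = tab["younger", "success"],
                 younger_n = sum(tab["younger", ]),
                 older_correct = tab["older", "success"],
                 older_n = sum(tab["older", ]),
                 fisher_p = tryCatch(fisher_exact_two_sided(tab),
                                     error = function(e) NA_real_),
                 stringsAsFactors = FALSE)
    }))

  structure(list(participants = participants,
                 first_intervention = first_intervention_summary(cohort),
                 strategy_table = strategy_table,
                 baselines = baselines,
                 efficiency = group_means,
                 contingency = contingency,
                 n_unclassifiable = sum(participants$strategy == "unclassifiable"),
                 seed = seed, mode = mode, min_contention = min_contention),
            class = "switchbox_analysis")
}

#' @export
print.switchbox_analysis <- function(x, digits = 3, ...) {
  cat("Switch-box cohort analysis\n")
  cat(sprintf("  %d participants (%d unclassifiable), optimality mode '%s'\n\n",
              nrow(x$participants), x$n_unclassifiable, x$mode))
  cat("First intervention (counts, % testing one switch):\n")
  fi <- x$first_intervention
  fi$test_one_pct <- round(fi$test_one_pct, 1)
  print(fi[, c("age_group", "condition", "n", "test_one", "test_multiple",
               "test_one_pct")], row.names = FALSE)
  cat("\nStrategy classification (bracketed = information-optimal):\n")
  st <- x$strategy_table
  st$cell <- sprintf("%d [%d]", st$count, st$info_optimal)
  st$proportion <- round(st$proportion, digits)
  print(st[, c("age_group", "condition", "strategy", "cell", "proportion")],
        row.names = FALSE)
  cat("\nMean intervention efficiency (participants vs simulated learners):\n")
  ef <- x$efficiency
  ef$mean_efficiency <- round(ef$mean_efficiency, digits)
  print(ef[, c("age_group", "condition", "learner", "mean_efficiency", "n")],
        row.names = FALSE)
  cat("\nGuess accuracy of test-multiple users (younger vs older):\n")
  ct <- x$contingency
  ct$fisher_p <- signif(ct$fisher_p, 4)
  print(ct, row.names = FALSE)
  invisible(x)
}

#' @export
summary.switchbox_analysis <- function(object, ...) {
  print(object, ...)
  cat(sprintf("\nOverall accuracy: %.1f%%; mean payout %.2f\n",
              100 * mean(object$participants$correct),
              mean(object$participants$payout)))
  invisible(object)
}

#' @export
plot.switchbox_analysis <- function(x, ...) {
  ef <- x$efficiency
  ef$cell <- paste(ef$age_group, ef$condition, sep = "\n")
  learners <- c("participants", "random", "test_one", "split_half")
  cols <- c(participants = "black", random = "blue", test_one = "red",
            split_half = "darkgreen")
  cells <- unique(ef$cell)
  graphics::plot(NULL, xlim = c(0.5, length(cells) + 0.5), ylim = c(0, 1.05),
                 xaxt = "n", xlab = "", ylab = "Mean efficiency (EIG / best EIG)",
                 main = "Intervention efficiency vs simulated learners", ...)
  graphics::axis(1, at = seq_along(cells), labels = cells, cex.axis = 0.8)
  for (j in seq_along(learners)) {
    sub <- ef[ef$learner == learners[j], ]
    xx <- match(sub$cell, cells) + (j - 2.5) * 0.12
    graphics::points(xx, sub$mean_efficiency, pch = 15, col = cols[learners[j]])
    graphics::arrows(xx, sub$ci_lower, xx, sub$ci_upper, angle = 90, code = 3,
                     length = 0.03, col = cols[learners[j]])
  }
  graphics::legend("bottomleft", legend = learners, col = cols[learners],
                   pch = 15, bty = "n", cex = 0.8)
  invisible(x)
}
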