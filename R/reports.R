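# Report-bundle entry points used by the command-line wrapper. Every numeric
# cell they emit comes from an exported operation; this layer only arranges
# output files.

write_manifest <- function(out_dir, seed, inputs = character(0)) {
  lines <- c(
    sprintf("package: switchbox %s",
            as.character(utils::packageVersion("switchbox"))),
    sprintf("seed: %s", seed),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("output_dir: %s", normalizePath(out_dir)),
    if (length(inputs)) sprintf("input: %s", inputs))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

#' Generate a synthetic cohort and write its trial logs
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [cohort_spec()]; `NULL` uses the defaults.
#' @param seed Integer seed (overrides the spec's seed).
#' @param include_strategy Write the planted-strategy column?
#' @return The cohort, invisibly. Writes `trials.csv`, `trials_guesses.csv`
#'   and `manifest.txt`.
#' @export
run_generate <- function(out_dir, spec = NULL, seed = 1L,
                         include_strategy = FALSE) {
  if (is.null(spec)) spec <- cohort_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  write_trial_log(cohort, file.path(out_dir, "trials.csv"),
                  include_strategy = include_strategy)
  write_manifest(out_dir, seed)
  invisible(cohort)
}

#' Analyze a trial log and write the report bundle
#'
#' @param log_path Path to a trial-log CSV (guesses file alongside).
#' @param out_dir Output directory.
#' @param seed Integer seed for baselines and bootstrap.
#' @return The `switchbox_analysis`, invisibly. Writes
#'   `first_intervention.csv`, `strategy_table.csv`,
#'   `participant_summary.csv`, `efficiency_comparison.csv`,
#'   `contingency.csv` and `manifest.txt`.
#' @export
run_analyze <- function(log_path, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_trial_log(log_path)
  an <- analyze_cohort(cohort, seed = seed)
  utils::write.csv(an$first_intervention,
                   file.path(out_dir, "first_intervention.csv"),
                   row.names = FALSE)
  utils::write.csv(an$strategy_table,
                   file.path(out_dir, "strategy_table.csv"), row.names = FALSE)
  utils::write.csv(an$participants,
                   file.path(out_dir, "participant_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(an$efficiency,
                   file.path(out_dir, "efficiency_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(an$contingency, file.path(out_dir, "contingency.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, seed, inputs = log_path)
  invisible(an)
}

#' Run the two-proportion Fisher power analysis and write a report
#'
#' @inheritParams fisher_power_simulation
#' @param out_dir Output directory; `NULL` skips writing.
#' @param target_power Planning target the estimate is compared against.
#' @return The `switchbox_power` object, invisibly.
#' @export
run_power <- function(p1 = 0.30, p2 = 0.70, n_per_group = 25L, alpha = 0.05,
                      replicates = 5000L, seed = 1L, out_dir = NULL,
                      target_power = 0.80) {
  pw <- fisher_power_simulation(p1, p2, n_per_group, alpha, replicates, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(
      p1 = p1, p2 = p2, n_per_group = n_per_group, alpha = alpha,
      replicates = replicates, power = pw$power, se = pw$se,
      target = target_power,
      meets_target = pw$power >= target_power), file.path(out_dir, "power.csv"),
      row.names = FALSE)
    write_manifest(out_dir, seed)
  }
  invisible(pw)
}

#' Simulate one policy session and print its trace
#'
#' @param kind Policy kind, see [policy_spec()].
#' @param condition Task condition.
#' @param target Hidden target switch.
#' @param seed Integer seed.
#' @return Data frame trace of the session, invisibly printed.
#' @export
run_simulate_policy <- function(kind = "split_half", condition = "sparse",
                                target = 6L, seed = 1L) {
  config <- task_config(condition)
  trials <- run_policy(policy_spec(kind, seed = seed), config, target)
  data.frame(
    trial = seq_along(trials),
    on_set = vapply(trials, function(tr) paste(tr$on_set, collapse = ","),
                    character(1)),
    lights_on = vapply(trials, `[[`, logical(1), "lights_on"),
    candidates_before = vapply(trials, function(tr)
      paste(tr$belief, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Exact expected reward of a policy under the token economy
#'
#' @inheritParams run_simulate_policy
#' @param stopping Stopping rule, see [expected_policy_payout()].
#' @param rounding Split-half rounding rule.
#' @return Expected payout (currency units).
#' @export
run_expected_reward <- function(kind = "test_one", condition = "dense",
                                stopping = "direct_hit", rounding = "ceil") {
  expected_policy_payout(policy_spec(kind, rounding = rounding),
                         task_config(condition), payout_rule(),
                         stopping = stopping)
}
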