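#' Specify a simulated learner
#'
#' Four reference learners used as baselines for participant efficiency:
#' \describe{
#'   \item{random}{turns each switch on independently with probability 0.5
#'     (the on-set may be empty);}
#'   \item{test_one}{turns on a single previously untested switch each trial,
#'     drawn uniformly; when every switch has been turned on at some point it
#'     falls back to untested candidates, then to any candidate;}
#'   \item{split_half}{turns on a uniformly drawn subset of the current
#'     candidate set of size half the candidates, rounded per `rounding`;}
#'   \item{greedy_eig}{turns on a uniformly drawn maximizer of expected
#'     information gain.}
#' }
#'
#' @param kind One of `"random"`, `"test_one"`, `"split_half"`, `"greedy_eig"`.
#' @param rounding `"ceil"` (default) or `"floor"`: how split-half rounds an
#'   odd candidate count.
#' @param seed Integer seed making a simulated session reproducible.
#' @param max_trials Maximum number of paid tests; defaults to the token
#'   budget of the task configuration at run time.
#' @return An object of class `switchbox_policy`.
#' @export
policy_spec <- function(kind = c("random", "test_one", "split_half", "greedy_eig"),
                        rounding = c("ceil", "floor"), seed = 1L,
                        max_trials = NULL) {
  kind <- match.arg(kind)
  rounding <- match.arg(rounding)
  if (!is.null(max_trials) && max_trials < 1L)
    stop("max_trials must be >= 1", call. = FALSE)
  structure(list(kind = kind, rounding = rounding, seed = as.integer(seed),
                 max_trials = max_trials),
            class = "switchbox_policy")
}

split_size <- function(m, rounding) {
  r <- if (rounding == "ceil") ceiling(m / 2) else floor(m / 2)
  max(1L, as.integer(r))
}

# sample() promotes a length-1 x to sample.int(x); guard against that.
sample_from <- function(x, size = 1L) {
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size)
}

#' Choose the next intervention under a policy
#'
#' Uses the current RNG stream; callers wanting reproducibility seed it
#' (as [run_policy()] does from `policy$seed`).
#'
#' @param policy A [policy_spec()].
#' @param belief Current candidate set (nonempty integer vector).
#' @param history List of previous trials (`on_set`, `lights_on`).
#' @param config A [task_config()].
#' @return Integer vector of switches to turn on.
#' @export
next_intervention <- function(policy, belief, history, config) {
  belief <- check_on_set(belief, config)
  if (length(belief) == 0L) stop("belief must be nonempty", call. = FALSE)
  n <- config$n_switches
  switch(policy$kind,
    random = which(stats::runif(n) < 0.5),
    test_one = {
      ever_on <- unique(unlist(lapply(history, `[[`, "on_set")))
      tested_singly <- unlist(lapply(history, function(tr)
        if (length(tr$on_set) == 1L) tr$on_set else NULL))
      pool <- setdiff(seq_len(n), ever_on)
      if (length(pool) == 0L) pool <- setdiff(belief, tested_singly)
      if (length(pool) == 0L) pool <- belief
      sample_from(pool)
    },
    split_half = sort(sample_from(belief, split_size(length(belief),
                                                     policy$rounding))),
    greedy_eig = {
      vals <- enumerate_intervention_values(belief, config)
      best <- max(vals$eig)
      idx <- which(vals$eig >= best - 1e-12)
      pick <- vals$on_set[[sample_from(idx)]]
      as.integer(strsplit(pick, ",", fixed = TRUE)[[1]])
    }
  )
}

#' Run a simulated learner to the end of a session
#'
#' Iterates choose / activate / update until the belief is a singleton or
#' the trial budget is exhausted, recording the pre-trial candidate set with
#' each trial. Reproducible: the session is driven by `policy$seed`.
#'
#' @param policy A [policy_spec()].
#' @param config A [task_config()].
#' @param target Hidden target switch index.
#' @return A list of trials; each trial has `on_set`, `lights_on` and
#'   `belief` (candidates in contention before the trial).
#' @export
run_policy <- function(policy, config, target) {
  target <- check_target(target, config)
  max_trials <- if (is.null(policy$max_trials)) config$n_tokens
                else as.integer(policy$max_trials)
  with_seed(policy$seed, {
    belief <- seq_len(config$n_switches)
    trials <- list()
    while (length(belief) > 1L && length(trials) < max_trials) {
      iv <- next_intervention(policy, belief, trials, config)
      obs <- simulate_outcome(config, target, iv)
      trials[[length(trials) + 1L]] <-
        c(make_trial(iv, obs), list(belief = belief))
      belief <- update_belief(belief, iv, obs, config)
    }
    trials
  })
}

#' Random learners matched to a cohort's trial counts
#'
#' For each participant, simulates a random intervener (each switch on with
#' probability 0.5) in the same condition and against the same target, forced
#' to perform exactly as many paid tests as that participant did — no early
#' stopping. Per-participant RNG streams are derived from `seed`, so the
#' matched cohort is reproducible.
#'
#' @param cohort A list of participant records (see [generate_cohort()]).
#' @param seed Integer seed.
#' @return A cohort of simulated participant records with planted strategy
#'   `"random"`.
#' @export
matched_random_cohort <- function(cohort, seed = 1L) {
  stopifnot(length(cohort) > 0L)
  base <- cohort_base_config(cohort)
  out <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    config <- task_config(p$condition, base$n_switches, base$n_tokens,
                          base$token_value)
    with_seed(derive_seed(seed, i), {
      belief <- seq_len(config$n_switches)
      trials <- vector("list", length(p$trials))
      for (t in seq_along(trials)) {
        iv <- which(stats::runif(config$n_switches) < 0.5)
        obs <- simulate_outcome(config, p$target, iv)
        trials[[t]] <- c(make_trial(iv, obs), list(belief = belief))
        belief <- update_belief(belief, iv, obs, config)
      }
      guess <- sample_from(belief)
      make_participant(
        id = paste0(p$id, "_rand"), age_group = p$age_group,
        condition = p$condition, target = p$target, trials = trials,
        guesses = data.frame(guess_index = 1L, guessed_switch = guess,
                             verified_correct = guess == p$target),
        strategy = "random", config = config
      )
    })
  })
  as_cohort(out, base)
}
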