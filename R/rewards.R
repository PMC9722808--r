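#' Token-economy payout rule
#'
#' Participants start with `n_tokens` tokens, pay one per test, and keep the
#' remaining tokens (each worth `token_value`) if their final answer is
#' correct. Under the default forfeit rule a wrong final guess forfeits the
#' monetary reward entirely; with `forfeit_on_wrong_final_guess = FALSE` the
#' remaining tokens are kept regardless (the reading in which participants
#' re-guess for free until correct).
#'
#' @param n_tokens Token budget (default 6).
#' @param token_value Value of one token (default 0.50 EUR).
#' @param forfeit_on_wrong_final_guess Logical (default `TRUE`).
#' @return An object of class `switchbox_payout_rule`.
#' @export
payout_rule <- function(n_tokens = 6L, token_value = 0.5,
                        forfeit_on_wrong_final_guess = TRUE) {
  stopifnot(n_tokens >= 1L, token_value > 0)
  structure(list(n_tokens = as.integer(n_tokens), token_value = token_value,
                 forfeit = isTRUE(forfeit_on_wrong_final_guess)),
            class = "switchbox_payout_rule")
}

#' Realized payout of a finished session
#'
#' @param n_tests Number of paid tests performed (0..`n_tokens`).
#' @param correct Was the final answer correct?
#' @param rule A [payout_rule()].
#' @return Payout in currency units.
#' @examples
#' realized_payout(1, TRUE, payout_rule())  # 2.50: the maximum reward
#' @export
realized_payout <- function(n_tests, correct, rule = payout_rule()) {
  n_tests <- as.integer(n_tests)
  if (is.na(n_tests) || n_tests < 0L || n_tests > rule$n_tokens)
    stop(sprintf("n_tests must be in 0..%d", rule$n_tokens), call. = FALSE)
  if (rule$forfeit && !isTRUE(correct)) return(0)
  (rule$n_tokens - n_tests) * rule$token_value
}

# Exact choice distribution of a policy in a given state: a list of
# list(on_set=, prob=). Mirrors next_intervention, but enumerated.
policy_choice_distribution <- function(policy, belief, ever_on, tested_singly,
                                       config) {
  n <- config$n_switches
  uniform <- function(sets) lapply(sets, function(s)
    list(on_set = as.integer(s), prob = 1 / length(sets)))
  switch(policy$kind,
    random = {
      sets <- c(list(integer(0)), all_on_sets(n))
      lapply(sets, function(s) list(on_set = as.integer(s), prob = 2^(-n)))
    },
    test_one = {
      pool <- setdiff(seq_len(n), ever_on)
      if (length(pool) == 0L) pool <- setdiff(belief, tested_singly)
      if (length(pool) == 0L) pool <- belief
      uniform(as.list(pool))
    },
    split_half = {
      if (length(belief) == 1L) return(uniform(list(belief)))
      r <- split_size(length(belief), policy$rounding)
      uniform(utils::combn(belief, r, simplify = FALSE))
    },
    greedy_eig = {
      sets <- all_on_sets(n)
      eig <- vapply(sets, function(s)
        expected_information_gain(belief, s, config), numeric(1))
      uniform(sets[eig >= max(eig) - 1e-12])
    }
  )
}

# Did this test identify the target directly (rather than by elimination)?
# Sparse: the lights came on and only one candidate can explain it.
# Dense: the lights stayed off with the candidate itself switched on.
direct_confirmation <- function(new_belief, on_set, lights_on, config) {
  if (length(new_belief) != 1L) return(FALSE)
  if (config$condition == "sparse") lights_on && new_belief %in% on_set
  else !lights_on && length(on_set) == 1L && on_set == new_belief
}

#' Exact expected payout of a policy
#'
#' Computes the exact expectation of the realized payout over the uniformly
#' random target and over the policy's own randomness (by exhaustive
#' averaging over its choice distribution at every reachable state), for one
#' of two stopping rules. `"certainty"` stops paying as soon as the candidate
#' set is a singleton, using elimination ("five tested switches all worked,
#' so it is the sixth"). `"direct_hit"` keeps paying until a test identifies
#' the target directly — in the dense condition until the tested switch
#' itself fails to turn the lights on — with no elimination shortcut on the
#' last switch. A session that exhausts the token budget earns nothing.
#'
#' @param policy A [policy_spec()] (its seed is irrelevant here: the
#'   expectation is exact).
#' @param config A [task_config()].
#' @param rule A [payout_rule()].
#' @param stopping `"direct_hit"` or `"certainty"`.
#' @return Expected payout in currency units.
#' @examples
#' cfg <- task_config("dense")
#' expected_policy_payout(policy_spec("test_one"), cfg,
#'                        stopping = "direct_hit")  # 1.25
#' @export
expected_policy_payout <- function(policy, config, rule = payout_rule(),
                                   stopping = c("direct_hit", "certainty")) {
  stopping <- match.arg(stopping)
  n <- config$n_switches
  max_trials <- if (is.null(policy$max_trials)) rule$n_tokens
                else min(policy$max_trials, rule$n_tokens)
  memo <- new.env(parent = emptyenv())

  value <- function(target, belief, ever_on, tested_singly, n_tests, confirmed) {
    done <- if (stopping == "certainty") length(belief) == 1L else confirmed
    if (done) return((rule$n_tokens - n_tests) * rule$token_value)
    if (n_tests >= max_trials) return(0)
    key <- paste(target, paste(belief, collapse = ","), n_tests, confirmed,
                 if (policy$kind == "test_one")
                   paste(paste(ever_on, collapse = ","),
                         paste(tested_singly, collapse = ","), sep = "|")
                 else "", sep = ";")
    if (!is.null(memo[[key]])) return(memo[[key]])
    choices <- policy_choice_distribution(policy, belief, ever_on,
                                          tested_singly, config)
    v <- 0
    for (ch in choices) {
      obs <- simulate_outcome(config, target, ch$on_set)
      nb <- update_belief(belief, ch$on_set, obs, config)
      conf <- confirmed || direct_confirmation(nb, ch$on_set, obs, config)
      v <- v + ch$prob *
        value(target, nb, sort(union(ever_on, ch$on_set)),
              if (length(ch$on_set) == 1L) sort(union(tested_singly, ch$on_set))
              else tested_singly,
              n_tests + 1L, conf)
    }
    memo[[key]] <- v
    v
  }

  mean(vapply(seq_len(n), function(target)
    value(target, seq_len(n), integer(0), integer(0), 0L, FALSE), numeric(1)))
}
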