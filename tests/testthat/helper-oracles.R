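# Independent oracles used to cross-check the package implementations.
# They deliberately use different mechanics (bitmasks, dhyper enumeration)
# from the code paths they verify.

# Outcome rule on bitmask representation: switches as bits 0..(n-1).
oracle_lights <- function(condition, target, mask) {
  tbit <- bitwShiftL(1L, target - 1L)
  if (condition == "sparse") bitwAnd(mask, tbit) != 0L
  else bitwAnd(mask, bitwNot(tbit)) != 0L
}

set_to_mask <- function(s) if (length(s) == 0L) 0L else
  sum(bitwShiftL(1L, as.integer(s) - 1L))

# EIG by explicit outcome enumeration over the uniform candidate set.
oracle_eig <- function(condition, candidates, on_set) {
  mask <- set_to_mask(on_set)
  pred <- vapply(candidates, function(h) oracle_lights(condition, h, mask),
                 logical(1))
  m <- length(candidates)
  h_term <- function(k) if (k > 0) (k / m) * log2(k) else 0
  log2(m) - h_term(sum(pred)) - h_term(m - sum(pred))
}

# Max EIG by brute force over every nonempty on-set of 1..n.
oracle_best <- function(condition, candidates, n) {
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    best <- max(best, oracle_eig(condition, candidates, s))
  }
  best
}

# Two-sided Fisher exact p by hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0L, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Replay a session and return the final candidate set.
replay_final_belief <- function(trials, config) {
  belief <- seq_len(config$n_switches)
  for (tr in trials)
    belief <- update_belief(belief, tr$on_set, tr$lights_on, config)
  belief
}

# Build a participant record list directly from a policy trace (test fixture).
fixture_participant <- function(id, config, target, trials, guess,
                                age_group = "older") {
  trials <- lapply(trials, function(tr)
    list(on_set = tr$on_set, lights_on = tr$lights_on))
  guesses <- data.frame(guess_index = 1L, guessed_switch = guess,
                        verified_correct = guess == target)
  structure(list(id = id, age_group = age_group,
                 condition = config$condition, target = target,
                 trials = trials, guesses = guesses,
                 payout = realized_payout(length(trials), guess == target,
                                          payout_rule(config$n_tokens,
                                                      config$token_value)),
                 strategy = NA_character_),
            class = "switchbox_participant")
}

fixture_cohort <- function(participants) {
  structure(participants, class = "switchbox_cohort",
            n_switches = 6L, n_tokens = 6L, token_value = 0.5)
}
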