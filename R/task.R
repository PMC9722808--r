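#' Task configuration for the switch-box search problem
#'
#' The box has `n_switches` switches and three lights. Exactly one hidden
#' target switch matters: in the `"sparse"` condition it is the only switch
#' that works (the lights come on iff it is among the switches turned on);
#' in the `"dense"` condition it is the only switch that is broken (the
#' lights come on iff any other switch is turned on). Each paid activation
#' of the box costs one token.
#'
#' @param condition `"sparse"` or `"dense"`.
#' @param n_switches Number of switches on the box (default 6).
#' @param n_tokens Token budget, i.e. maximum number of paid tests (default 6).
#' @param token_value Value of one unspent token, in euro (default 0.50).
#' @return An object of class `switchbox_config`.
#' @examples
#' cfg <- task_config("sparse")
#' simulate_outcome(cfg, target = 2, on_set = c(1, 2, 3))
#' @export
task_config <- function(condition = c("sparse", "dense"), n_switches = 6L,
                        n_tokens = 6L, token_value = 0.5) {
  condition <- match.arg(condition)
  n_switches <- as.integer(n_switches)
  n_tokens <- as.integer(n_tokens)
  if (is.na(n_switches) || n_switches < 2L)
    stop("n_switches must be an integer >= 2", call. = FALSE)
  if (is.na(n_tokens) || n_tokens < 1L)
    stop("n_tokens must be an integer >= 1", call. = FALSE)
  if (!is.numeric(token_value) || token_value <= 0)
    stop("token_value must be > 0", call. = FALSE)
  structure(
    list(condition = condition, n_switches = n_switches,
         n_tokens = n_tokens, token_value = token_value),
    class = "switchbox_config"
  )
}

#' @export
print.switchbox_config <- function(x, ...) {
  cat(sprintf(
    "Switch-box task: %s condition, %d switches, %d tokens x %.2f EUR\n",
    x$condition, x$n_switches, x$n_tokens, x$token_value))
  invisible(x)
}

# Validate a set of switch indices against the configuration. Empty sets are
# legal (all switches off) but degenerate: they can never separate hypotheses.
check_on_set <- function(on_set, config) {
  if (length(on_set) == 0L) return(integer(0))
  on_set <- as.integer(on_set)
  if (anyNA(on_set) || any(on_set < 1L) || any(on_set > config$n_switches))
    stop(sprintf("switch indices must be in 1..%d", config$n_switches),
         call. = FALSE)
  sort(unique(on_set))
}

check_target <- function(target, config) {
  target <- as.integer(target)
  if (length(target) != 1L || is.na(target) || target < 1L ||
      target > config$n_switches)
    stop(sprintf("target must be a single switch index in 1..%d",
                 config$n_switches), call. = FALSE)
  target
}

#' Deterministic outcome of one paid activation
#'
#' Sparse condition: the lights come on iff the working target switch is in
#' the on-set. Dense condition: every switch except the broken target works,
#' and a single working switch in the on position suffices, so the lights
#' come on iff the on-set contains any switch other than the target.
#'
#' @param config A [task_config()].
#' @param target Index of the hidden target switch.
#' @param on_set Integer vector of switch indices turned on (may be empty).
#' @return Logical scalar: did the lights come on?
#' @export
simulate_outcome <- function(config, target, on_set) {
  target <- check_target(target, config)
  on_set <- check_on_set(on_set, config)
  if (config$condition == "sparse") {
    target %in% on_set
  } else {
    any(on_set != target)
  }
}

#' Update the candidate set after observing one test
#'
#' The ideal observer keeps the set of target hypotheses consistent with all
#' evidence so far (uniform prior). A candidate survives iff it predicts the
#' observed outcome under the deterministic outcome rule.
#'
#' @param belief Integer vector of candidate target switches (nonempty).
#' @param on_set Switches turned on in the test.
#' @param lights_on Observed outcome (logical).
#' @param config A [task_config()].
#' @return The surviving candidate set (sorted integer vector).
#' @export
update_belief <- function(belief, on_set, lights_on, config) {
  belief <- check_on_set(belief, config)
  if (length(belief) == 0L) stop("belief must be nonempty", call. = FALSE)
  on_set <- check_on_set(on_set, config)
  pred <- vapply(belief, function(h) simulate_outcome(config, h, on_set),
                 logical(1))
  out <- belief[pred == lights_on]
  if (length(out) == 0L)
    stop("contradiction: observed outcome is inconsistent with every candidate",
         call. = FALSE)
  out
}

#' Candidate sets in contention before each trial
#'
#' Replays a participant's session from the full switch set and returns the
#' belief state *before* each paid test, the quantity the strategy
#' classifier conditions on ("switches still in contention").
#'
#' @param trials List of trials, each a list with elements `on_set` (integer
#'   vector) and `lights_on` (logical), in chronological order.
#' @param config A [task_config()].
#' @return A list of integer vectors, one per trial.
#' @export
candidates_in_contention <- function(trials, config) {
  belief <- seq_len(config$n_switches)
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    out[[i]] <- belief
    belief <- tryCatch(
      update_belief(belief, trials[[i]]$on_set, trials[[i]]$lights_on, config),
      error = function(e) stop(sprintf("trial %d: %s", i, conditionMessage(e)),
                               call. = FALSE)
    )
  }
  out
}

# Final belief after all trials (used by the generator and anomaly flags).
final_belief <- function(trials, config) {
  belief <- seq_len(config$n_switches)
  for (tr in trials)
    belief <- update_belief(belief, tr$on_set, tr$lights_on, config)
  belief
}

#' Shannon entropy of a uniform candidate set
#'
#' @param belief Integer vector of candidates (nonempty).
#' @return Entropy in bits: `log2(length(belief))`.
#' @export
belief_entropy <- function(belief) {
  if (length(belief) == 0L) stop("belief must be nonempty", call. = FALSE)
  log2(length(belief))
}

# Construct one trial record.
make_trial <- function(on_set, lights_on) {
  list(on_set = as.integer(on_set), lights_on = isTRUE(lights_on))
}
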