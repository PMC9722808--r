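#' Expected information gain of an intervention
#'
#' Prior entropy of the uniform candidate set minus the outcome-probability
#' weighted entropy of the updated set, where the outcome distribution is
#' induced by the uniform belief through the deterministic outcome rule
#' (`0 * log 0 = 0`). An intervention whose outcome is certain under the
#' current belief has zero EIG.
#'
#' @param belief Integer vector of candidate target switches (nonempty).
#' @param on_set Switches turned on (may be empty; empty sets are
#'   uninformative by construction).
#' @param config A [task_config()].
#' @return Expected information gain in bits, in `[0, belief_entropy(belief)]`.
#' @examples
#' cfg <- task_config("sparse")
#' expected_information_gain(1:6, c(1, 2, 3), cfg)  # 1 bit
#' @export
expected_information_gain <- function(belief, on_set, config) {
  belief <- check_on_set(belief, config)
  if (length(belief) == 0L) stop("belief must be nonempty", call. = FALSE)
  on_set <- check_on_set(on_set, config)
  pred <- vapply(belief, function(h) simulate_outcome(config, h, on_set),
                 logical(1))
  n <- length(belief)
  n_on <- sum(pred)
  n_off <- n - n_on
  post <- 0
  if (n_on > 0) post <- post + (n_on / n) * log2(n_on)
  if (n_off > 0) post <- post + (n_off / n) * log2(n_off)
  log2(n) - post
}

#' Exact EIG of every nonempty intervention
#'
#' Brute-force enumeration of all `2^n_switches - 1` nonempty on-sets,
#' guarded to `n_switches <= 16`.
#'
#' @inheritParams expected_information_gain
#' @return A data frame with columns `on_set` (comma-separated indices),
#'   `size` and `eig` (bits), one row per nonempty on-set.
#' @export
enumerate_intervention_values <- function(belief, config) {
  if (config$n_switches > 16L)
    stop("enumeration limited to n_switches <= 16", call. = FALSE)
  belief <- check_on_set(belief, config)
  sets <- all_on_sets(config$n_switches)
  eig <- vapply(sets, function(s) expected_information_gain(belief, s, config),
                numeric(1))
  data.frame(
    on_set = vapply(sets, function(s) paste(s, collapse = ","), character(1)),
    size = lengths(sets),
    eig = eig,
    stringsAsFactors = FALSE
  )
}

#' Best attainable EIG given the current belief
#'
#' Closed-form maximum over all nonempty on-sets. In the sparse condition the
#' optimum turns on as close as possible to half the candidates (the
#' split-half strategy); in the dense condition only single still-candidate
#' switches are informative, all with equal EIG. Equality with the
#' brute-force enumeration is asserted in the test suite.
#'
#' @inheritParams expected_information_gain
#' @return Maximum EIG in bits (0 when one candidate remains).
#' @export
best_intervention_value <- function(belief, config) {
  belief <- check_on_set(belief, config)
  if (length(belief) == 0L) stop("belief must be nonempty", call. = FALSE)
  m <- length(belief)
  if (m == 1L) return(0)
  if (config$condition == "sparse") {
    k <- floor(m / 2)
    log2(m) - (k / m) * log2(k) - ((m - k) / m) * ifelse(m - k > 0, log2(m - k), 0)
  } else {
    # test one candidate: lights off with prob 1/m (that candidate broken)
    log2(m) - ((m - 1) / m) * log2(m - 1)
  }
}

#' Efficiency of a chosen intervention
#'
#' The chosen intervention's EIG as a proportion of the best attainable EIG
#' under the same belief. Undefined (`NA`) when nothing can be learned
#' (best EIG is 0); such trials are excluded from averages.
#'
#' @inheritParams expected_information_gain
#' @return A ratio in `[0, 1]`, or `NA_real_` when undefined.
#' @export
efficiency_of_choice <- function(belief, on_set, config) {
  best <- best_intervention_value(belief, config)
  if (best <= 0) return(NA_real_)
  expected_information_gain(belief, on_set, config) / best
}

#' Mean per-trial efficiency of one participant's session
#'
#' Tracks the true posterior through the participant's actual evidence and
#' averages the defined per-trial efficiencies.
#'
#' @param trials List of trials (`on_set`, `lights_on`) in order.
#' @param config A [task_config()].
#' @return A list with `per_trial` (numeric vector, `NA` where undefined),
#'   `mean` (mean of defined values, `NA` if none) and `n_defined`.
#' @export
participant_efficiency <- function(trials, config) {
  beliefs <- candidates_in_contention(trials, config)
  per_trial <- vapply(seq_along(trials), function(i)
    efficiency_of_choice(beliefs[[i]], trials[[i]]$on_set, config), numeric(1))
  defined <- per_trial[!is.na(per_trial)]
  list(per_trial = per_trial,
       mean = if (length(defined)) mean(defined) else NA_real_,
       n_defined = length(defined))
}
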