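#' Specification of a synthetic participant cohort
#'
#' Describes the cohort the generator emulates: one row per design cell
#' (age group x condition) with the cell size, the mixture over planted
#' strategies, and the cell's inference noise — the probability that a
#' simulant gives up integrating evidence once few candidates remain and
#' guesses uniformly among them instead of testing on to the certain answer.
#'
#' The default cells mirror the observed cohort sizes and first-test
#' proportions of the study design this generator emulates (test-one
#' probabilities 62.5/79.3/39.3/60.9% for younger-sparse / younger-dense /
#' older-sparse / older-dense); the remaining probability mass is split 80/20
#' between split-half and strategy-switching simulants, and inference noise
#' defaults to 0.5 (younger) vs 0.1 (older). These are documented starting
#' approximations, not ground truth.
#'
#' @param cells Data frame with columns `age_group`, `condition`, `n`,
#'   `p_test_one`, `p_split_half`, `p_other`, `inference_noise`.
#' @param guess_threshold Candidate-set size at or below which a noisy
#'   simulant guesses instead of testing on (default 2).
#' @param seed Integer seed; every participant draws from a stream derived
#'   from it.
#' @return An object of class `switchbox_cohort_spec`.
#' @export
cohort_spec <- function(cells = default_cells(), guess_threshold = 2L,
                        seed = 1L) {
  needed <- c("age_group", "condition", "n", "p_test_one", "p_split_half",
              "p_other", "inference_noise")
  if (!all(needed %in% names(cells)))
    stop("cells must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  mix <- cells$p_test_one + cells$p_split_half + cells$p_other
  if (any(abs(mix - 1) > 1e-8))
    stop("strategy mixture must sum to 1 in every cell", call. = FALSE)
  if (any(cells$inference_noise < 0 | cells$inference_noise > 1))
    stop("inference_noise must be in [0, 1]", call. = FALSE)
  if (any(!cells$condition %in% c("sparse", "dense")))
    stop("condition must be 'sparse' or 'dense'", call. = FALSE)
  structure(list(cells = cells, guess_threshold = as.integer(guess_threshold),
                 seed = as.integer(seed)),
            class = "switchbox_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cells <- function() {
  data.frame(
    age_group = c("younger", "younger", "older", "older"),
    condition = c("sparse", "dense", "sparse", "dense"),
    n = c(24L, 29L, 28L, 23L),
    p_test_one = c(0.625, 0.793, 0.393, 0.609),
    p_split_half = 0.8 * (1 - c(0.625, 0.793, 0.393, 0.609)),
    p_other = 0.2 * (1 - c(0.625, 0.793, 0.393, 0.609)),
    inference_noise = c(0.5, 0.5, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
}

# Normalize trials to (on_set, lights_on), validate outcome consistency, and
# compute the realized payout from the first guess.
make_participant <- function(id, age_group, condition, target, trials,
                             guesses, strategy, config) {
  trials <- lapply(trials, function(tr) {
    obs <- simulate_outcome(config, target, tr$on_set)
    if (!identical(obs, tr$lights_on))
      stop(sprintf("participant %s: recorded outcome inconsistent with task model",
                   id), call. = FALSE)
    make_trial(tr$on_set, tr$lights_on)
  })
  correct <- nrow(guesses) > 0L && guesses$verified_correct[1]
  payout <- realized_payout(length(trials), correct,
                            payout_rule(config$n_tokens, config$token_value))
  structure(list(id = id, age_group = age_group, condition = condition,
                 target = as.integer(target), trials = trials,
                 guesses = guesses, payout = payout, strategy = strategy),
            class = "switchbox_participant")
}

as_cohort <- function(participants, base) {
  structure(participants, class = "switchbox_cohort",
            n_switches = base$n_switches, n_tokens = base$n_tokens,
            token_value = base$token_value)
}

cohort_base_config <- function(cohort) {
  list(n_switches = attr(cohort, "n_switches") %||% 6L,
       n_tokens = attr(cohort, "n_tokens") %||% 6L,
       token_value = attr(cohort, "token_value") %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.switchbox_cohort <- function(x, ...) {
  cat(sprintf("Synthetic switch-box cohort: %d participants (%d switches, %d tokens)\n",
              length(x), attr(x, "n_switches"), attr(x, "n_tokens")))
  invisible(x)
}

# One simulated session under a planted strategy. Assumes the RNG stream is
# already seeded for this participant.
simulate_session <- function(strategy, config, target, noise, guess_threshold) {
  noisy <- stats::runif(1) < noise
  belief <- seq_len(config$n_switches)
  trials <- list()
  pol_multi <- policy_spec("split_half", seed = 1L)  # seed unused here
  pol_one <- policy_spec("test_one", seed = 1L)
  while (length(belief) > 1L && length(trials) < config$n_tokens) {
    if (noisy && length(belief) <= guess_threshold) break
    iv <- switch(strategy,
      test_one = next_intervention(pol_one, belief, trials, config),
      split_half = next_intervention(pol_multi, belief, trials, config),
      other_switcher = {
        if (length(trials) %% 2L == 0L)
          next_intervention(pol_one, belief, trials, config)
        else if (length(belief) >= 2L)
          sort(sample_from(belief, max(2L, split_size(length(belief), "ceil"))))
        else belief
      })
    obs <- simulate_outcome(config, target, iv)
    trials[[length(trials) + 1L]] <- make_trial(iv, obs)
    belief <- update_belief(belief, iv, obs, config)
  }
  # guessing: uniform over current candidates; the free verification of a
  # wrong guess eliminates it, and the simulant re-guesses until correct
  remaining <- belief
  guesses <- list()
  repeat {
    g <- sample_from(remaining)
    ok <- g == target
    guesses[[length(guesses) + 1L]] <-
      data.frame(guess_index = length(guesses) + 1L, guessed_switch = g,
                 verified_correct = ok)
    if (ok) break
    remaining <- setdiff(remaining, g)
  }
  list(trials = trials, guesses = do.call(rbind, guesses))
}

#' Generate a synthetic participant cohort
#'
#' For each participant: draw the hidden target uniformly, draw a planted
#' strategy from the cell mixture, simulate the session under that strategy
#' (a strategy-switching simulant alternates single- and multi-switch tests),
#' apply the guess threshold and inference noise, verify guesses against the
#' true target and compute the realized payout. Fully reproducible: the same
#' spec and seed give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param n_switches,n_tokens,token_value Task parameters shared by all cells.
#' @return An object of class `switchbox_cohort`: a list of participant
#'   records with task parameters as attributes.
#' @export
generate_cohort <- function(spec = cohort_spec(), n_switches = 6L,
                            n_tokens = 6L, token_value = 0.5) {
  stopifnot(inherits(spec, "switchbox_cohort_spec"))
  base <- list(n_switches = as.integer(n_switches),
               n_tokens = as.integer(n_tokens), token_value = token_value)
  participants <- list()
  idx <- 0L
  for (r in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[r, ]
    config <- task_config(cell$condition, base$n_switches, base$n_tokens,
                          base$token_value)
    for (k in seq_len(cell$n)) {
      idx <- idx + 1L
      id <- sprintf("P%03d", idx)
      participants[[idx]] <- with_seed(derive_seed(spec$seed, idx), {
        target <- sample.int(config$n_switches, 1L)
        strategy <- sample(c("test_one", "split_half", "other_switcher"), 1L,
                           prob = c(cell$p_test_one, cell$p_split_half,
                                    cell$p_other))
        ses <- simulate_session(strategy, config, target,
                                cell$inference_noise, spec$guess_threshold)
        make_participant(id, cell$age_group, cell$condition, target,
                         ses$trials, ses$guesses, strategy, config)
      })
    }
  }
  as_cohort(participants, base)
}

#' Write / read a cohort as CSV trial logs
#'
#' The trial log has one row per paid test: `participant_id`, `age_group`,
#' `condition`, `target_switch`, `trial_index`, `s1..sN` (0/1 switch states)
#' and `lights_on` (0/1). A companion guesses file has one row per guess:
#' `participant_id`, `guess_index`, `guessed_switch`, `verified_correct`.
#' The planted strategy is written only when `include_strategy = TRUE`
#' (off by default, mimicking real logs); payouts are recomputed on read
#' from the payout rule, so the round trip is lossless.
#'
#' @param cohort A `switchbox_cohort`.
#' @param path Path of the trial-log CSV.
#' @param guesses_path Path of the guesses CSV; defaults to `path` with a
#'   `_guesses.csv` suffix.
#' @param include_strategy Write the planted-strategy column?
#' @return `write_trial_log` returns the two paths invisibly;
#'   `read_trial_log` returns a `switchbox_cohort`.
#' @export
write_trial_log <- function(cohort, path, guesses_path = NULL,
                            include_strategy = FALSE) {
  base <- cohort_base_config(cohort)
  if (is.null(guesses_path))
    guesses_path <- sub("\\.csv$", "_guesses.csv", path)
  n <- base$n_switches
  rows <- lapply(cohort, function(p) {
    if (length(p$trials) == 0L) return(NULL)
    m <- t(vapply(p$trials, function(tr) {
      s <- integer(n); s[tr$on_set] <- 1L
      c(s, as.integer(tr$lights_on))
    }, integer(n + 1L)))
    d <- data.frame(participant_id = p$id, age_group = p$age_group,
                    condition = p$condition, target_switch = p$target,
                    trial_index = seq_along(p$trials),
                    stringsAsFactors = FALSE)
    colnames(m) <- c(paste0("s", seq_len(n)), "lights_on")
    d <- cbind(d, as.data.frame(m))
    if (include_strategy) d$planted_strategy <- p$strategy
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  grows <- lapply(cohort, function(p) {
    if (is.null(p$guesses) || nrow(p$guesses) == 0L) return(NULL)
    cbind(data.frame(participant_id = p$id, stringsAsFactors = FALSE),
          p$guesses)
  })
  utils::write.csv(do.call(rbind, grows), guesses_path, row.names = FALSE)
  invisible(c(path, guesses_path))
}

#' @rdname write_trial_log
#' @param n_switches Expected number of switch columns; `NULL` infers it from
#'   the file, and a mismatch with an explicit value is a parse error.
#' @param n_tokens,token_value Task parameters used to recompute payouts.
#' @export
read_trial_log <- function(path, guesses_path = NULL, n_switches = NULL,
                           n_tokens = 6L, token_value = 0.5) {
  if (is.null(guesses_path))
    guesses_path <- sub("\\.csv$", "_guesses.csv", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  scols <- grep("^s[0-9]+$", names(d), value = TRUE)
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  if (length(scols) == 0L)
    stop("parse error: no switch-state columns (s1..sN) found", call. = FALSE)
  if (!is.null(n_switches) && length(scols) != n_switches)
    stop(sprintf("parse error: expected %d switch columns, found %d",
                 n_switches, length(scols)), call. = FALSE)
  n <- length(scols)
  needed <- c("participant_id", "age_group", "condition", "target_switch",
              "trial_index", "lights_on")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("parse error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c(scols, "lights_on")) {
    bad <- which(!d[[col]] %in% c(0L, 1L))
    if (length(bad))
      stop(sprintf("parse error: line %d: column %s must be 0 or 1",
                   bad[1] + 1L, col), call. = FALSE)
  }
  bad <- which(d$target_switch < 1L | d$target_switch > n)
  if (length(bad))
    stop(sprintf("parse error: line %d: target_switch out of range",
                 bad[1] + 1L), call. = FALSE)
  g <- if (file.exists(guesses_path))
    utils::read.csv(guesses_path, stringsAsFactors = FALSE)
  else stop("parse error: guesses file not found: ", guesses_path,
            call. = FALSE)
  gneeded <- c("participant_id", "guess_index", "guessed_switch",
               "verified_correct")
  gmissing <- setdiff(gneeded, names(g))
  if (length(gmissing))
    stop("parse error: guesses file missing column(s): ",
         paste(gmissing, collapse = ", "), call. = FALSE)
  g$verified_correct <- as.logical(g$verified_correct)

  base <- list(n_switches = n, n_tokens = as.integer(n_tokens),
               token_value = token_value)
  ids <- unique(d$participant_id)
  participants <- lapply(ids, function(id) {
    rows <- d[d$participant_id == id, ]
    rows <- rows[order(rows$trial_index), ]
    config <- task_config(rows$condition[1], n, base$n_tokens,
                          base$token_value)
    trials <- lapply(seq_len(nrow(rows)), function(i)
      make_trial(which(unlist(rows[i, scols]) == 1L),
                 rows$lights_on[i] == 1L))
    guesses <- g[g$participant_id == id,
                 c("guess_index", "guessed_switch", "verified_correct")]
    guesses <- guesses[order(guesses$guess_index), ]
    rownames(guesses) <- NULL
    make_participant(id, rows$age_group[1], rows$condition[1],
                     rows$target_switch[1], trials, guesses,
                     if ("planted_strategy" %in% names(rows))
                       rows$planted_strategy[1] else NA_character_,
                     config)
  })
  as_cohort(participants, base)
}
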