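---
title: "Models and methods behind switchbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind switchbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchbox)
```

## The task and the ideal observer

A box has `n_switches` switches (default 6) and a bank of lights. One hidden
target switch matters. In the *sparse* condition the target is the only
working switch, so an activation turns the lights on iff the target is among
the switches set to on. In the *dense* condition the target is the only
broken switch and a single working switch suffices, so the lights come on iff
any non-target switch is on. Every activation costs one of six tokens, each
worth €0.50 if kept; a correct final answer banks the unspent tokens.

Because the system is deterministic and exactly one hypothesis is true, the
ideal observer is a candidate-elimination machine: the belief state is the
set of target hypotheses consistent with every outcome so far, with a uniform
prior over it. `update_belief()` keeps exactly the candidates that predict
the observed outcome and raises a contradiction error if none does (which, on
real logs, indicates a corrupted record, since the generator can never
produce one). Beliefs shrink monotonically and the true target always
survives; both are property-tested. A probability-vector belief would add
nothing here — elimination is exact — which is why candidate sets are the
representation throughout.

## Expected information gain and efficiency

For belief $C$ and intervention $a$ (the set of switches turned on),

$$\mathrm{EIG}(a) = \log_2 |C| \;-\; \sum_{o \in \{\text{on,off}\}}
  P(o \mid a, C)\, \log_2 |C_o|,$$

where $C_o$ is the subset of candidates predicting outcome $o$ and
$P(o \mid a, C) = |C_o|/|C|$. The two conditions shape the EIG landscape
very differently, and the package exploits the closed forms while verifying
them against brute force:

- *sparse*: only $k = |a \cap C|$ matters; the maximizers are exactly the
  near-even splits $k \in \{\lfloor |C|/2 \rfloor, \lceil |C|/2 \rceil\}$
  (1 bit from six candidates). This is asserted by exhaustive enumeration
  for candidate sets up to size 8.
- *dense*: any intervention containing two or more switches, or any
  already-exonerated switch, always turns the lights on and teaches nothing;
  the only informative tests are single still-candidate switches, each worth
  $\log_2 m - \frac{m-1}{m}\log_2(m-1)$ bits for $m$ candidates (0.650 bits
  from six).

`best_intervention_value()` uses these closed forms; the test suite checks it
against `enumerate_intervention_values()` over every belief for up to six
switches and over sampled beliefs of every size for seven and eight (full
enumeration beyond that is redundant by switch relabeling). Per-trial
*efficiency* is chosen EIG over best EIG, tracked against the true posterior
(full evidence integration). Trials where the best EIG is zero are excluded
from averages rather than scored 1: a learner who tests after the answer is
certain should not be credited with an optimal choice, and exclusion cannot
inflate group means. Ties among optimal interventions are broken uniformly at
random by the policies under their seed; the efficiency metric itself only
needs the value.

## Simulated learners

Four reference policies generate complete sessions (`run_policy()`), stopping
at certainty or after six paid tests: *random* (each switch on independently
with p = .5, so even the empty set occurs), *test-one* (a uniformly drawn,
previously untested single switch; when all switches have been on at some
point it falls back to untested candidates, then any candidate), *split-half*
(a uniform subset of the current candidates of half their number; odd counts
round up by default, configurable to round down), and *greedy-EIG* (a uniform
EIG maximizer; in sparse it reaches certainty within
$\lceil \log_2 6 \rceil = 3$ tests, which is asserted exhaustively). In the
dense condition the split-half policy operates on the candidate *target* set
— the natural transfer of "possibly working" to "possibly broken" — which
makes it maximally ineffective there, exactly the contrast the task is built
around. `matched_random_cohort()` forces one random session per participant
with the same condition, target and trial count, without early stopping,
for a like-for-like efficiency baseline. Whether real test-one learners draw
switches in a fixed or a random order is unknowable from the logs; random
order is used. Randomness is organized as one global seed with
per-participant streams derived deterministically from it, so cohorts are
reproducible regardless of iteration order.

## Strategy classification

Sessions are labeled from the trials where the choice is diagnostic: those
with at least four candidates still in contention (`eligible_trials()`).
*Test one* means every eligible test used exactly one switch, *test multiple*
means every eligible test used more than one, *other* is everything mixed. A
session with no eligible trial (possible only for empty sessions at the
default threshold, since the first trial always sees the full set) is
reported *unclassifiable* and excluded from tables.

The information-optimality flag has two modes. The default `"rule"` mode is
the bracketed-count criterion used in strategy figures: in sparse, a first
eligible test of 2–4 switches followed by eligible tests that turn on half of
the switches still in contention (rounded either way, drawn from the
candidates); in dense, a new single switch every time. `"strict_eig"` instead
demands the exact EIG maximum on every eligible trial. The two deliberately
diverge: 2- and 4-switch openings from six candidates pass the rule at 0.918
bits against the optimal 1.0, and the suite asserts this divergence. The rule
mode is the default because the bracket criterion is itself defined that way;
strict mode is offered for sensitivity analysis.

Session anomaly flags are stated approximations (their original
operationalization is not public): `early_stop` marks a first guess made with
two or more candidates still alive, and `unnecessary_tests` marks any paid
test that could teach nothing (best EIG 0) or chose to learn nothing (chosen
EIG 0). Guess events are stored apart from paid tests and never enter EIG or
classification: verifying a guess costs no token.

## Token economics

`realized_payout()` implements the 6-token economy: a correct final answer
banks €0.50 per unspent token (maximum €2.50 after one lucky test); a wrong
final answer forfeits the money under the default rule (configurable, since
the procedure also allows re-guessing). `expected_policy_payout()` computes
exact expectations by recursing over every reachable belief state, averaging
exhaustively over the policy's choice distribution and the uniformly random
target, under two stopping rules:

- *direct hit*: the learner pays until a test names the target directly —
  in dense, until the tested switch itself fails to light the lights; there
  is no elimination shortcut on the last switch. Test-one then costs
  (1+2+...+6)/6 = 3.5 tests on average, hence the €1.25 expected return in
  the dense condition.
- *certainty*: the learner stops as soon as one candidate remains. Test-one
  in dense improves to E[tests] = 10/3 (€1.3333); split-half in sparse needs
  1 + 5/3 tests (€1.6667).

An entropy bound caps what any certainty-stopping policy can earn in sparse:
E[tests] ≥ log2 6 ≈ 2.585, so expected payouts cannot exceed ≈ €1.71. The
often-quoted ≈ €1.90 for the ideal sparse strategy is therefore not
reproducible under either stopping rule implemented here; the function is
exposed so users can evaluate alternative policy/stopping readings, and the
test suite asserts the bound rather than the unreachable figure. Monte-Carlo
agreement between `run_policy()` sessions and the exact recursion is checked
at 15,000 seeded sessions per case within three standard errors.

## Contingency tests, bootstrap, power

`fisher_exact_two_sided()` uses the standard two-sided convention — the sum
of hypergeometric probabilities of margin-consistent tables no more probable
than the observed one — via `stats::fisher.test`, cross-checked in the tests
against an independent `dhyper` enumeration. Conventions differ between
software packages, which is why the choice is pinned down and documented.
For the 15/15 vs 2/6 accuracy contrast this gives p = 0.0025 (printed as
.002); for 17/19 vs 3/7 it gives p ≈ 0.028, and no standard two-sided
convention yields the .003 sometimes quoted for that table — the value is
reported as computed.

`bootstrap_mean_ci()` is a seeded percentile bootstrap for group means
(coverage is property-tested on Gaussian data, allowing the small-sample
undercoverage typical of the percentile method). `fisher_power_simulation()`
draws group success counts binomially, evaluates the Fisher test on a
precomputed p-value grid, and reports the rejection fraction with its
Monte-Carlo standard error; type-I control, monotonicity in effect and group
size, and agreement with exact binomial enumeration are all tested.

The sample-size planning question — power at 25 participants per group,
α = .05, for a 40-percentage-point difference in strategy proportions — needs
a placement of that difference. The package defaults to the symmetric
0.30 vs 0.70, the conservative choice: it is the placement that *minimizes*
Fisher-test power among all 40-point gaps, and both simulation and exact
enumeration put that minimum just below the conventional 80% target (≈ 78%).
More extreme placements (baselines below 0.15 or above 0.45) do clear 80%.
`p1`/`p2` are arguments precisely so planners can explore this; the default
is not moved to flatter the target.

## The synthetic cohort generator

`generate_cohort()` stands in for the unavailable raw logs. Per participant
it draws a uniform hidden target and a planted strategy from the cell's
mixture (test-one, split-half, or a switcher that alternates single- and
multi-switch tests), simulates the session, and models the guess stage with
two knobs:

- `guess_threshold` (default 2): the candidate-set size at which a simulant
  is tempted to stop testing and guess;
- `inference_noise`: the probability that, at that point, the simulant
  guesses uniformly from the current candidates instead of testing on to the
  certain answer. Wrong guesses are disproved by the free verification and
  re-guessed from the surviving candidates; the payout keys on the first
  guess under the forfeit rule.

This locates the younger children's deficit in inference reliability, not in
intervention choice, and makes accuracy strictly decrease in the noise
parameter for test-multiple simulants — the mechanism of the younger/older
accuracy gap, not a fit to its specific counts. Default cell sizes
(24/29/28/23) and test-one mixture weights (62.5/79.3/39.3/60.9%) start from
the observed first-intervention proportions of the cohort this generator
emulates, with the remaining mass split 80/20 between split-half and switcher
simulants and noise 0.5 (younger) vs 0.1 (older); all are configuration, not
ground truth. The CSV schema (`participant_id, age_group, condition,
target_switch, trial_index, s1..s6, lights_on` plus a guesses file) is an
invention, documented as such, with strict parse errors naming the offending
line and column.

What the generator deliberately does not emulate: reaction times,
token-insertion events, incomplete or excluded sessions, multi-cause or
interacting switches, and any stochasticity in the box itself. Passing
pipeline tests on synthetic cohorts therefore demonstrates correctness of
the analysis machinery under the task's stated mechanics — not that real
children behave like the planted mixtures.

## Numerical and scale choices

EIG uses `0 log 0 = 0` and a `1e-12` tie tolerance for maximizer sets;
optimality checks use `1e-9`. Enumeration of interventions is guarded to 16
switches. Currency is reported to 2 decimals, bits to 3, p-values to 4 in
reports. Test problem sizes are chosen to keep the suite quick while leaving
Monte-Carlo tolerances honest: exhaustive checks run at 6–8 switches, policy
orderings use 300 sessions per policy, payout agreement 15,000 sessions per
case, power checks 2,000–5,000 replicates, bootstrap coverage 400
experiments; each tolerance is the 3-standard-error band implied by its own
sample size.

## Known limitations

Beliefs are hard candidate sets: a trembling-hand or probabilistic-outcome
extension would need a different observer. The strategy taxonomy conditions
on a fixed contention threshold (4 of 6), so it does not transfer unchanged
to other switch counts. Expected-payout recursion assumes the policy's
choice distribution depends only on the tracked state (candidates, tested
switches), which covers the four built-in learners but not history-dependent
policies in general. The `other_switcher` simulant is one concrete
instantiation of "mixed" behavior; real mixed strategies are more varied.
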