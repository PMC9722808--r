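#' Two-sided Fisher exact test for a 2x2 table
#'
#' Standard two-sided convention: the p-value is the sum, over all tables
#' with the observed margins, of hypergeometric probabilities no larger than
#' that of the observed table (as implemented by [stats::fisher.test()];
#' an independent hypergeometric enumeration backs this in the test suite).
#'
#' @param table A 2x2 matrix of non-negative counts (rows = groups,
#'   columns = success/failure), or the count `a` with `b`, `c`, `d`.
#' @param b,c,d Remaining cell counts when `table` is given as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(15, 0, 2, 4), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(table))
    table <- matrix(c(table, b, c, d), 2, byrow = TRUE)
  if (!all(dim(table) == 2L) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is all zero", call. = FALSE)
  stats::fisher.test(table)$p.value
}

# p-value lookup for all (x1, x2) success counts at fixed group size;
# degenerate margins carry no evidence against the null (p = 1).
fisher_p_grid <- function(n_per_group) {
  n <- n_per_group
  grid <- matrix(1, n + 1L, n + 1L)
  for (x1 in 0:n) for (x2 in 0:n) {
    tot <- x1 + x2
    if (tot > 0L && tot < 2L * n)
      grid[x1 + 1L, x2 + 1L] <-
        stats::fisher.test(matrix(c(x1, n - x1, x2, n - x2), 2,
                                  byrow = TRUE))$p.value
  }
  grid
}

#' Simulation-based power of the two-sided Fisher exact test
#'
#' Estimates the power to detect a difference between two independent
#' proportions: each replicate draws group success counts
#' `Binomial(n_per_group, p1)` and `Binomial(n_per_group, p2)` and rejects
#' when the two-sided Fisher exact p-value is below `alpha`. Reproducible
#' under `seed`; the Monte-Carlo standard error of the estimate is reported.
#'
#' @param p1,p2 True success proportions in the two groups.
#' @param n_per_group Participants per group.
#' @param alpha Significance level (default 0.05).
#' @param replicates Number of simulated experiments (default 5000).
#' @param seed Integer seed.
#' @return An object of class `switchbox_power`: a list with `power`, `se`,
#'   and the design fields.
#' @examples
#' fisher_power_simulation(0.3, 0.7, 25, replicates = 1000, seed = 1)
#' @export
fisher_power_simulation <- function(p1, p2, n_per_group, alpha = 0.05,
                                    replicates = 5000L, seed = 1L) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, alpha > 0, alpha < 1,
            n_per_group >= 1, replicates >= 1)
  grid <- fisher_p_grid(n_per_group)
  rej <- with_seed(seed, {
    x1 <- stats::rbinom(replicates, n_per_group, p1)
    x2 <- stats::rbinom(replicates, n_per_group, p2)
    grid[cbind(x1 + 1L, x2 + 1L)] < alpha
  })
  power <- mean(rej)
  structure(list(power = power,
                 se = sqrt(power * (1 - power) / replicates),
                 p1 = p1, p2 = p2, n_per_group = n_per_group, alpha = alpha,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "switchbox_power")
}

#' @export
print.switchbox_power <- function(x, ...) {
  cat(sprintf(
    "Fisher exact power: %.3f (MC SE %.4f)\n  p1 = %.2f, p2 = %.2f, n = %d/group, alpha = %.3f, %d replicates\n",
    x$power, x$se, x$p1, x$p2, x$n_per_group, x$alpha, x$replicates))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Numeric vector (nonempty).
#' @param level Confidence level (default 0.95).
#' @param resamples Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_mean_ci <- function(values, level = 0.95, resamples = 2000L,
                              seed = 1L) {
  if (length(values) == 0L || all(is.na(values)))
    stop("values must be nonempty", call. = FALSE)
  values <- values[!is.na(values)]
  means <- with_seed(seed, vapply(seq_len(resamples), function(i)
    mean(values[sample.int(length(values), replace = TRUE)]), numeric(1)))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Build a 2x2 success table from grouped outcomes
#'
#' @param group Factor-like vector with the grouping (two expected levels).
#' @param success Logical vector of the same length.
#' @return A 2x2 integer matrix (rows = groups, columns = success/failure).
#'   Warns when fewer than two groups are present (degenerate table).
#' @export
proportion_table <- function(group, success) {
  stopifnot(length(group) == length(success), length(group) > 0L)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    warning("degenerate table: fewer than two groups present")
  tab <- table(group, factor(!success, levels = c(FALSE, TRUE),
                             labels = c("success", "failure")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
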