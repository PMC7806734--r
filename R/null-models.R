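#' Chance probability that a 4-entry window visits 4 distinct arms
#'
#' Under memoryless uniform exploration each entry is uniform over the
#' `n_arms - 1` arms other than the current one (the maze center forces a
#' change of arm). The probability that 4 consecutive entries cover 4
#' distinct arms is computed by exhaustive enumeration of all equally likely
#' 3-step continuations from an arbitrary starting arm — `(n_arms - 1)^3`
#' outcomes, 27 for the 4-arm maze, of which 6 complete the remaining three
#' arms, giving 2/9 (the "22% chance level").
#'
#' @param n_arms Number of arms (>= 3); 4 for this maze. The 3-arm analogue
#'   (classical Y-maze with window size 3) is obtained with `n_arms = 3`.
#' @return The exact probability as a numeric scalar.
#' @examples
#' window_success_probability()        # 2/9
#' round(100 * window_success_probability())  # 22
#' @export
window_success_probability <- function(n_arms = 4L) {
  stopifnot(n_arms >= 3L)
  arms <- seq_len(n_arms)
  start <- arms[1L]
  steps <- n_arms - 1L                # window size = n_arms entries
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_arms - 1L)), steps)))
  ok <- apply(grid, 1L, function(idx) {
    path <- start
    for (i in idx) {
      path <- c(path, setdiff(arms, path[length(path)])[i])
    }
    length(unique(path)) == n_arms
  })
  mean(ok)
}

#' Expected alternation percentage under the null at finite N
#'
#' By linearity of expectation over the N - 3 overlapping windows, the
#' expected alternation percentage with the entries-minus-2 denominator is
#' `100 * (N - 3) * (2/9) / (N - 2)`, approaching 22.2% as N grows.
#'
#' @param n_entries Number of entries N >= 4 (vectorized).
#' @param denominator See [percent_alternation()].
#' @return Expected percentage(s).
#' @export
expected_alternation_percent <- function(n_entries,
                                         denominator = c("entries_minus_2",
                                                         "windows")) {
  denominator <- match.arg(denominator)
  if (any(n_entries < 4L)) stop("n_entries must be at least 4")
  p <- window_success_probability()
  denom <- if (denominator == "entries_minus_2") n_entries - 2 else n_entries - 3
  100 * (n_entries - 3) * p / denom
}

#' Simulate an arm-entry sequence under the uniform null
#'
#' First arm uniform over the four; each subsequent arm uniform over the
#' three others, so the sequence contains no consecutive repeats by
#' construction. The RNG state of the caller is untouched.
#'
#' @param n_entries Sequence length N >= 1.
#' @param seed Integer seed (required for reproducibility).
#' @param labels Arm vocabulary (4 labels).
#' @return Character vector of length `n_entries`.
#' @export
simulate_null_sequence <- function(n_entries, seed,
                                   labels = arm_labels("color")) {
  stopifnot(n_entries >= 1L, length(labels) == 4L)
  local_seed(seed, {
    out <- character(n_entries)
    out[1L] <- sample(labels, 1L)
    if (n_entries > 1L) {
      draws <- sample.int(3L, n_entries - 1L, replace = TRUE)
      for (i in 2:n_entries) {
        out[i] <- setdiff(labels, out[i - 1L])[draws[i - 1L]]
      }
    }
    out
  })
}

#' Monte-Carlo test of an observed alternation percentage against chance
#'
#' Simulates the null distribution of [percent_alternation()] at the observed
#' number of entries and reports the null mean and SD together with a
#' two-sided empirical p-value using the add-one (permutation-style)
#' estimator: `p = (1 + #{null as or more extreme}) / (n_sims + 1)`, with the
#' tail chosen by the sign of the deviation from the null mean, doubled and
#' capped at 1.
#'
#' @param observed_percent Observed alternation percentage.
#' @param n_entries Entries N >= 4 behind the observation.
#' @param n_sims Number of null simulations (default 10000).
#' @param seed Integer seed.
#' @param denominator See [percent_alternation()].
#' @return List: `null_mean`, `null_sd`, `empirical_p`, `n_sims`,
#'   `analytic_mean` (the closed-form expectation).
#' @export
null_alternation_test <- function(observed_percent, n_entries,
                                  n_sims = 10000L, seed = 1L,
                                  denominator = c("entries_minus_2",
                                                  "windows")) {
  denominator <- match.arg(denominator)
  if (n_entries < 4L) stop("n_entries must be at least 4")
  stopifnot(n_sims >= 1L)
  null_pct <- local_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      seq <- character(n_entries)
      labels <- arm_labels("color")
      seq[1L] <- sample(labels, 1L)
      for (j in 2:n_entries) {
        seq[j] <- sample(setdiff(labels, seq[j - 1L]), 1L)
      }
      percent_alternation(seq, denominator = denominator)$percent
    }, numeric(1))
  })
  null_mean <- mean(null_pct)
  side <- if (observed_percent >= null_mean) {
    sum(null_pct >= observed_percent)
  } else {
    sum(null_pct <= observed_percent)
  }
  p <- min(1, 2 * (1 + side) / (n_sims + 1))
  list(null_mean = null_mean, null_sd = stats::sd(null_pct),
       empirical_p = p, n_sims = n_sims,
       analytic_mean = expected_alternation_percent(n_entries, denominator))
}
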