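#' Collapse consecutive same-arm re-entries
#'
#' A mouse that exits into the center and re-enters the arm it just left
#' produces consecutive duplicate labels. Transitions and alternation are
#' defined only between distinct arms, so duplicates are collapsed (run-length
#' reduction) before scoring; the number of collapsed repeats is reported so
#' total raw entries can still be tracked. The operation is idempotent.
#'
#' @param seq Character vector of arm labels (may be empty).
#' @return List with `sequence` (no two consecutive labels equal) and
#'   `n_collapsed` (number of removed repeats).
#' @examples
#' collapse_reentries(c("R", "R", "G", "B"))
#' @export
collapse_reentries <- function(seq) {
  seq <- as.character(seq)
  if (length(seq) == 0L) {
    return(list(sequence = character(0), n_collapsed = 0L))
  }
  check_arm_sequence(seq)
  keep <- c(TRUE, seq[-1L] != seq[-length(seq)])
  list(sequence = seq[keep], n_collapsed = sum(!keep))
}

#' Percent spontaneous alternation
#'
#' An alternation is a sequential visit of the four different arms without
#' returning to a previously visited arm: a length-4 sliding window
#' (overlapping, stride 1) over the entry sequence whose four labels are all
#' distinct. The percentage reports the number of such windows relative to
#' the total number of arm entries minus 2 — the denominator used when this
#' assay was described, kept as the default for comparability even though a
#' sequence of N entries has only N - 3 windows. The `"windows"` denominator
#' (N - 3, so a perfect sequence scores 100) is exposed as an option.
#'
#' @param seq Arm-label sequence with no consecutive repeats (apply
#'   [collapse_reentries()] first), or a `vis4m_session`. Length N >= 4.
#' @param denominator `"entries_minus_2"` (default) or `"windows"`.
#' @return List of class `alternation_result`: `n_entries`, `n_windows`,
#'   `n_successes`, `denominator`, `percent`.
#' @examples
#' percent_alternation(c("B", "W", "R", "G", "B", "G", "W", "R", "B"))
#' @export
percent_alternation <- function(seq, denominator = c("entries_minus_2", "windows")) {
  denominator <- match.arg(denominator)
  seq <- if (inherits(seq, "vis4m_session")) arm_sequence(seq)
         else as.character(seq)
  n <- length(seq)
  if (n < 4L) stop("sequence too short for alternation (need at least 4 entries)")
  if (any(seq[-1L] == seq[-n])) {
    stop("sequence has consecutive repeats; apply collapse_reentries() first")
  }
  n_windows <- n - 3L
  ok <- vapply(seq_len(n_windows), function(i) {
    length(unique(seq[i:(i + 3L)])) == 4L
  }, logical(1))
  n_successes <- sum(ok)
  denom <- if (denominator == "entries_minus_2") n - 2L else n - 3L
  structure(
    list(n_entries = n, n_windows = n_windows, n_successes = n_successes,
         denominator = denom, percent = 100 * n_successes / denom),
    class = "alternation_result"
  )
}

#' @export
print.alternation_result <- function(x, ...) {
  cat(sprintf("alternation: %.1f%% (%d of %d windows distinct, denominator %d, N = %d)\n",
              x$percent, x$n_successes, x$n_windows, x$denominator, x$n_entries))
  invisible(x)
}

#' Percent entries per arm
#'
#' @param seq Arm-label sequence or `vis4m_session` (raw entries, i.e. not
#'   collapsed, so that re-entries count towards arm preference).
#' @param labels Arm vocabulary; arms never entered report 0.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_entries <- function(seq, labels = NULL) {
  if (inherits(seq, "vis4m_session")) {
    labels <- labels %||% arm_labels(seq$mode)
    seq <- seq$events$arm
  }
  seq <- as.character(seq)
  if (length(seq) == 0L) stop("empty sequence: no entries to tally")
  labels <- labels %||% sort(unique(seq))
  check_arm_sequence(seq, labels)
  counts <- table(factor(seq, levels = labels))
  stats::setNames(100 * as.vector(counts) / length(seq), labels)
}

#' Percent time per arm
#'
#' Dwell time per arm is the sum of (exit - entry) over its events; the
#' percentage base is the total time inside the four arms (time in the center
#' zone is excluded from the denominator, so the four percentages sum to 100).
#'
#' @param x A `vis4m_session`, or a data frame with columns `arm`,
#'   `t_enter`, `t_exit`.
#' @param labels Arm vocabulary; arms never entered report 0.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_time <- function(x, labels = NULL) {
  if (inherits(x, "vis4m_session")) {
    labels <- labels %||% arm_labels(x$mode)
    events <- x$events
  } else {
    events <- as.data.frame(x)
  }
  stopifnot(all(c("arm", "t_enter", "t_exit") %in% names(events)))
  labels <- labels %||% sort(unique(as.character(events$arm)))
  dwell <- events$t_exit - events$t_enter
  total <- sum(dwell)
  if (!(total > 0)) stop("zero total dwell time")
  by_arm <- tapply(dwell, factor(events$arm, levels = labels), sum,
                   default = 0)
  stats::setNames(100 * as.vector(by_arm) / total, labels)
}

#' Transition profile: unidirectional and bidirectional percentages
#'
#' Tallies the N - 1 consecutive ordered pairs of a collapsed entry sequence
#' over the 12 ordered distinct-arm transition types, and folds them into the
#' 6 unordered (bidirectional) types. Percentages are relative to the total
#' number of transitions.
#'
#' @param seq Arm-label sequence with no consecutive repeats, or a
#'   `vis4m_session` (collapsed automatically). Length N >= 2.
#' @param labels Arm vocabulary (defaults to the session's, else the color
#'   set when the sequence uses it, else the sorted labels present).
#' @return Object of class `transition_profile`: `labels`, `uni_counts` (12,
#'   named by `"from>to"`), `total_transitions`, `uni_percent`, `bi_percent`
#'   (6, named by `"a:b"`).
#' @examples
#' transition_profile(c("R", "G", "B", "W", "R"))
#' @export
transition_profile <- function(seq, labels = NULL) {
  if (inherits(seq, "vis4m_session")) {
    labels <- labels %||% arm_labels(seq$mode)
    seq <- arm_sequence(seq)
  } else {
    seq <- as.character(seq)
  }
  n <- length(seq)
  if (n < 2L) stop("no transitions: need at least 2 entries")
  if (any(seq[-1L] == seq[-n])) {
    stop("sequence has consecutive repeats; apply collapse_reentries() first")
  }
  if (is.null(labels)) {
    labels <- if (all(seq %in% arm_labels("color"))) arm_labels("color")
              else sort(unique(seq))
  }
  if (length(labels) != 4L) stop("transition profile requires a 4-arm label set")
  check_arm_sequence(seq, labels)

  op <- ordered_arm_pairs(labels)
  keys <- pair_key_ordered(seq[-n], seq[-1L])
  uni_counts <- stats::setNames(integer(nrow(op)), op$pair)
  tab <- table(keys)
  uni_counts[names(tab)] <- as.integer(tab)
  total <- n - 1L
  uni_percent <- 100 * uni_counts / total

  up <- unordered_arm_pairs(labels)
  bi_percent <- stats::setNames(
    uni_percent[pair_key_ordered(up$a, up$b)] +
      uni_percent[pair_key_ordered(up$b, up$a)],
    up$pair
  )
  structure(
    list(labels = labels, uni_counts = uni_counts,
         total_transitions = total, uni_percent = uni_percent,
         bi_percent = bi_percent),
    class = "transition_profile"
  )
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf("<transition_profile> %d transitions over arms {%s}\n",
              x$total_transitions, paste(x$labels, collapse = ", ")))
  nz <- x$uni_percent[x$uni_counts > 0]
  if (length(nz)) {
    cat(paste(sprintf("  %s %5.1f%%", names(nz), nz), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Select the most or least frequent transition quartile
#'
#' Chord diagrams display either the most frequent (upper Q4 quartile) or the
#' least frequent (lower Q1 quartile) unidirectional transitions: the top or
#' bottom 3 of the 12 types. Ties are broken deterministically by the
#' canonical pair order (alphabetical on origin, then destination).
#'
#' @param profile A `transition_profile`.
#' @param which `"Q4_most_frequent"` or `"Q1_least_frequent"`.
#' @return Character vector of 3 ordered-pair keys (`"from>to"`).
#' @export
select_quartile_transitions <- function(profile,
                                        which = c("Q4_most_frequent",
                                                  "Q1_least_frequent")) {
  which <- match.arg(which)
  stopifnot(inherits(profile, "transition_profile"))
  pct <- profile$uni_percent           # already in canonical pair order
  decreasing <- which == "Q4_most_frequent"
  ord <- order(if (decreasing) -pct else pct, seq_along(pct))
  names(pct)[ord[1:3]]
}
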