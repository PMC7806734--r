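# Exact step likelihood of the exploration model.
#
# The probability of the next arm given the last <= k entries is obtained by
# marginalizing over the recall/confusion outcomes of each remembered entry.
# Tag sets are tracked as bitmasks over the four arms (16 states), folding
# one memory entry at a time, so the marginalization is exact and cheap.

choice_prob_given_memory <- function(params, memory, conf) {
  labels <- params$labels
  current <- memory[length(memory)]
  m <- params$memory_strength
  # distribution over tag subsets (bitmask 0..15), folded per memory entry
  dist <- numeric(16L)
  dist[1L] <- 1
  for (a in memory) {
    new <- numeric(16L)
    pa <- conf[a, ]
    for (s in which(dist > 0)) {
      p <- dist[s]
      new[s] <- new[s] + p * (1 - m)
      for (r in 1:4) {
        tagged <- bitwOr(s - 1L, bitwShiftL(1L, r - 1L)) + 1L
        new[tagged] <- new[tagged] + p * m * pa[r]
      }
    }
    dist <- new
  }
  cand <- setdiff(labels, current)
  probs <- stats::setNames(numeric(3L), cand)
  for (s in which(dist > 0)) {
    mask <- s - 1L
    tagged <- labels[bitwAnd(bitwShiftR(mask, 0:3), 1L) == 1L]
    w <- candidate_weights(params, current, tagged)
    probs <- probs + dist[s] * w
  }
  probs
}

# Aggregate (memory context, choice) counts over sessions: the likelihood
# only depends on these sufficient counts, making repeated evaluation cheap.
context_counts <- function(sequences, memory_span) {
  ctx <- character(0)
  cho <- character(0)
  for (seq in sequences) {
    n <- length(seq)
    if (n < 2L) next
    for (t in 1:(n - 1L)) {
      mem <- seq[max(1L, t - memory_span + 1L):t]
      ctx <- c(ctx, paste(mem, collapse = "|"))
      cho <- c(cho, seq[t + 1L])
    }
  }
  out <- as.data.frame(table(context = ctx, choice = cho),
                       stringsAsFactors = FALSE)
  out[out$Freq > 0L, , drop = FALSE]
}

neg_log_likelihood <- function(params, counts) {
  conf <- confusion_matrix(params)
  contexts <- unique(counts$context)
  nll <- 0
  for (cx in contexts) {
    mem <- strsplit(cx, "|", fixed = TRUE)[[1L]]
    pr <- choice_prob_given_memory(params, mem, conf)
    sub <- counts[counts$context == cx, , drop = FALSE]
    p <- pr[sub$choice]
    if (any(!is.finite(log(p)))) return(Inf)
    nll <- nll - sum(sub$Freq * log(p))
  }
  nll
}

set_free_params <- function(params, free_names, values) {
  for (i in seq_along(free_names)) {
    nm <- free_names[i]
    v <- values[i]
    if (nm == "memory_strength") params$memory_strength <- v
    else if (nm == "avoidance") params$avoidance <- v
    else if (nm %in% names(params$discriminability)) {
      params$discriminability[nm] <- v
    } else if (nm %in% params$labels) {
      params$preference[nm] <- exp(v)   # log scale, positivity
    } else stop("unknown free parameter: ", nm)
  }
  params
}

free_param_bounds <- function(params, free_names) {
  lower <- upper <- start <- numeric(length(free_names))
  for (i in seq_along(free_names)) {
    nm <- free_names[i]
    if (nm %in% params$labels) {
      lower[i] <- -5; upper[i] <- 5
      start[i] <- log(params$preference[nm])
    } else {
      lower[i] <- 1e-6; upper[i] <- 1 - 1e-6
      start[i] <- if (nm == "memory_strength") params$memory_strength
                  else if (nm == "avoidance") params$avoidance
                  else params$discriminability[nm]
      start[i] <- min(max(start[i], lower[i]), upper[i])
    }
  }
  list(lower = lower, upper = upper, start = start)
}

#' Fit exploration parameters to observed sessions by maximum likelihood
#'
#' Maximizes the exact step-wise likelihood of the observed arm choices under
#' the generative model of [exploration_params()], over a chosen subset of
#' free parameters, holding the rest at the values in `fixed_params`. Free
#' parameters are named `"memory_strength"`, `"avoidance"`, a pair key such
#' as `"B:W"` (discriminability), or an arm label (log preference weight).
#' 95% confidence intervals come from the profile likelihood (chi-squared
#' cutoff, other free parameters re-optimized).
#'
#' @param sessions List of [session()] objects (or character sequences).
#' @param fixed_params An [exploration_params()] giving every fixed value.
#' @param free_params Character vector of parameter names to estimate.
#' @param true_params Optional [exploration_params()] holding the generating
#'   values (for recovery experiments; adds a `true` column).
#' @return Object of class `recovery_report`: tibble with columns
#'   `parameter`, `estimate`, `ci_lo`, `ci_hi` (and `true` when available),
#'   plus attributes `loglik` and `n_steps`.
#' @examples
#' \donttest{
#' p <- exploration_params(discriminability = c("B:W" = 0.3))
#' seqs <- lapply(1:50, function(i) simulate_arm_sequence(p, 30, seed = i))
#' fit_exploration_params(seqs, exploration_params(), "B:W")
#' }
#' @export
fit_exploration_params <- function(sessions, fixed_params, free_params,
                                   true_params = NULL) {
  stopifnot(inherits(fixed_params, "exploration_params"),
            length(free_params) >= 1L)
  sequences <- lapply(sessions, arm_sequence)
  counts <- context_counts(sequences, fixed_params$memory_span)
  n_steps <- sum(counts$Freq)
  if (n_steps < 10L * length(free_params)) {
    warning("very few observed choices for the number of free parameters; ",
            "estimates may be unstable and intervals wide")
  }
  b <- free_param_bounds(fixed_params, free_params)
  nll_at <- function(values) {
    neg_log_likelihood(set_free_params(fixed_params, free_params, values),
                       counts)
  }
  if (length(free_params) == 1L) {
    opt <- stats::optimize(function(v) nll_at(v),
                           lower = b$lower, upper = b$upper, tol = 1e-6)
    est <- opt$minimum
    nll_min <- opt$objective
  } else {
    opt <- stats::optim(b$start, nll_at, method = "L-BFGS-B",
                        lower = b$lower, upper = b$upper)
    est <- opt$par
    nll_min <- opt$value
  }
  cutoff <- nll_min + stats::qchisq(0.95, df = 1) / 2

  profile_nll <- function(i, v) {
    if (length(free_params) == 1L) return(nll_at(v))
    others <- setdiff(seq_along(free_params), i)
    fn <- function(ov) {
      vals <- numeric(length(free_params))
      vals[i] <- v
      vals[others] <- ov
      nll_at(vals)
    }
    stats::optim(est[others], fn, method = "L-BFGS-B",
                 lower = b$lower[others], upper = b$upper[others])$value
  }
  ci <- t(vapply(seq_along(free_params), function(i) {
    f <- function(v) profile_nll(i, v) - cutoff
    lo <- if (f(b$lower[i]) > 0) {
      tryCatch(stats::uniroot(f, c(b$lower[i], est[i]))$root,
               error = function(e) b$lower[i])
    } else b$lower[i]
    hi <- if (f(b$upper[i]) > 0) {
      tryCatch(stats::uniroot(f, c(est[i], b$upper[i]))$root,
               error = function(e) b$upper[i])
    } else b$upper[i]
    c(lo, hi)
  }, numeric(2)))

  report <- tibble::tibble(
    parameter = free_params,
    estimate = ifelse(free_params %in% fixed_params$labels, exp(est), est),
    ci_lo = ifelse(free_params %in% fixed_params$labels, exp(ci[, 1]), ci[, 1]),
    ci_hi = ifelse(free_params %in% fixed_params$labels, exp(ci[, 2]), ci[, 2])
  )
  if (!is.null(true_params)) {
    report$true <- unname(vapply(free_params, function(nm) {
      if (nm == "memory_strength") true_params$memory_strength
      else if (nm == "avoidance") true_params$avoidance
      else if (nm %in% names(true_params$discriminability)) {
        true_params$discriminability[[nm]]
      } else true_params$preference[[nm]]
    }, numeric(1)))
  }
  structure(report, class = c("recovery_report", class(report)),
            loglik = -nll_min, n_steps = n_steps)
}
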