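#' Generative parameters of the synthetic explorer
#'
#' The simulator is a semi-Markov stand-in for a mouse freely exploring the
#' four-arm maze. At every step the animal leaves its current arm and picks
#' one of the three other arms with weight
#' `preference(b) * avoidance^[b remembered as recently visited]`. Memory
#' works on the last `memory_span` entries (including the current arm): each
#' is recalled with probability `memory_strength`, and a recalled visit to
#' arm `a` is misremembered as another arm `b` with probability
#' `(1 - d(a,b)) / 3` — so pairwise discriminability `d` below 1 makes the
#' animal fail to tell the two arms of a pair apart, which selectively
#' collapses that pair's bidirectional transitions while leaving overall
#' activity untouched. Entry times follow a renewal process with exponential
#' inter-entry intervals (`entry_rate` per minute) and exponential dwell
#' times truncated at the next entry and at session end.
#'
#' @param preference Positive weights, one per arm (named or in label
#'   order). Default uniform.
#' @param memory_strength Recall probability `m` in `[0, 1]`.
#' @param memory_span Number of recent entries kept in memory (default 3,
#'   the alternation window minus one).
#' @param avoidance Multiplier `eps` in `[0, 1]` applied to remembered arms'
#'   weights (0 = perfect avoidance, 1 = no avoidance).
#' @param discriminability Named vector over the 6 unordered pair keys
#'   (`"a:b"`), values in `[0, 1]`; missing pairs default to 1 (never
#'   confused).
#' @param entry_rate Mean entries per minute (> 0).
#' @param dwell_mean Mean in-arm dwell in seconds (> 0).
#' @param duration_s Session length in seconds (default 300).
#' @param labels Arm vocabulary (default color mode).
#' @return Object of class `exploration_params`.
#' @export
exploration_params <- function(preference = NULL, memory_strength = 0.85,
                               memory_span = 3L, avoidance = 0.25,
                               discriminability = NULL, entry_rate = 6,
                               dwell_mean = 6, duration_s = 300,
                               labels = arm_labels("color")) {
  stopifnot(length(labels) == 4L)
  labels <- sort(labels)
  if (is.null(preference)) preference <- stats::setNames(rep(1, 4), labels)
  if (is.null(names(preference))) names(preference) <- labels
  preference <- preference[labels]
  stopifnot(all(preference > 0),
            memory_strength >= 0, memory_strength <= 1,
            memory_span >= 1L, avoidance >= 0, avoidance <= 1,
            entry_rate > 0, dwell_mean > 0, duration_s > 0)
  pairs <- unordered_arm_pairs(labels)$pair
  d <- stats::setNames(rep(1, length(pairs)), pairs)
  if (!is.null(discriminability)) {
    bad <- setdiff(names(discriminability), pairs)
    if (length(bad) > 0L) stop("unknown pair key(s): ", paste(bad, collapse = ", "))
    stopifnot(all(discriminability >= 0), all(discriminability <= 1))
    d[names(discriminability)] <- discriminability
  }
  structure(
    list(labels = labels, preference = preference,
         memory_strength = memory_strength, memory_span = as.integer(memory_span),
         avoidance = avoidance, discriminability = d,
         entry_rate = entry_rate, dwell_mean = dwell_mean,
         duration_s = duration_s),
    class = "exploration_params"
  )
}

#' Preset parameter sets emulating the study phenotypes
#'
#' `"WT"` emulates a wild-type animal: strong working memory, mild red-arm
#' (dark) preference, full pairwise discriminability — cohort mean
#' alternation in the mid-40s percent. `"AD"` emulates the transgenic
#' phenotype: higher activity, weaker memory, stronger dark preference and
#' reduced blue/white and grey-equivalent discriminability
#' (`d(B,W) = 0.35`, `d(G,W) = 0.6`) — cohort mean alternation near the
#' low-20s chance level, with a selective blue-white transition deficit.
#'
#' @param genotype `"WT"` or `"AD"`.
#' @return An [exploration_params()] object.
#' @export
exploration_preset <- function(genotype = c("WT", "AD")) {
  genotype <- match.arg(genotype)
  if (genotype == "WT") {
    exploration_params(
      preference = c(B = 1, G = 1, R = 1.6, W = 1),
      memory_strength = 0.85, avoidance = 0.25,
      entry_rate = 6, dwell_mean = 6
    )
  } else {
    exploration_params(
      preference = c(B = 1, G = 1, R = 2.2, W = 1),
      memory_strength = 0.55, avoidance = 0.35,
      discriminability = c("B:W" = 0.35, "G:W" = 0.6),
      entry_rate = 7.5, dwell_mean = 5
    )
  }
}

# P(remembered identity = r | visit to arm a): confusion kernel of the
# discriminability parameters. Rows index the visited arm, columns the
# remembered identity.
confusion_matrix <- function(params) {
  labels <- params$labels
  k <- matrix(0, 4, 4, dimnames = list(labels, labels))
  for (a in labels) {
    for (b in labels) {
      if (a != b) k[a, b] <- (1 - params$discriminability[pair_key_unordered(a, b)]) / 3
    }
  }
  diag(k) <- 1 - rowSums(k)
  k
}

# candidate weights given a set of remembered ("tagged") arms; falls back to
# raw preference when avoidance annihilates every candidate
candidate_weights <- function(params, current, tagged) {
  cand <- setdiff(params$labels, current)
  w <- params$preference[cand]
  w[cand %in% tagged] <- w[cand %in% tagged] * params$avoidance
  if (sum(w) <= 0) w <- params$preference[cand]
  w / sum(w)
}

# one stochastic arm choice; memory = last <= k entries including current
draw_next_arm <- function(params, memory, conf) {
  current <- memory[length(memory)]
  tagged <- character(0)
  for (a in memory) {
    if (stats::runif(1) < params$memory_strength) {
      r <- sample(params$labels, 1L, prob = conf[a, ])
      tagged <- c(tagged, r)
    }
  }
  w <- candidate_weights(params, current, unique(tagged))
  sample(names(w), 1L, prob = w)
}

#' Simulate an arm-entry label sequence
#'
#' Runs the choice model of [exploration_params()] for a fixed number of
#' entries, without timing information. With `memory_strength = 0` and
#' uniform preference this is exactly the memoryless uniform null of
#' [simulate_null_sequence()].
#'
#' @param params An [exploration_params()] object.
#' @param n_entries Number of entries to draw (>= 1).
#' @param seed Integer seed.
#' @return Character vector of arm labels (no consecutive repeats).
#' @export
simulate_arm_sequence <- function(params, n_entries, seed) {
  stopifnot(inherits(params, "exploration_params"), n_entries >= 1L)
  conf <- confusion_matrix(params)
  local_seed(seed, {
    out <- character(n_entries)
    out[1L] <- sample(params$labels, 1L,
                      prob = params$preference / sum(params$preference))
    if (n_entries > 1L) {
      for (i in 2:n_entries) {
        mem <- out[max(1L, i - params$memory_span):(i - 1L)]
        out[i] <- draw_next_arm(params, mem, conf)
      }
    }
    out
  })
}

#' Simulate one full session (entries with times)
#'
#' @param params An [exploration_params()] object.
#' @param seed Integer seed.
#' @param mouse_id,genotype,sex,age_months,condition Session metadata.
#' @return A [session()] object; deterministic given `seed`.
#' @examples
#' s <- simulate_session(exploration_preset("WT"), seed = 7)
#' percent_alternation(s)
#' @export
simulate_session <- function(params, seed, mouse_id = "sim",
                             genotype = c("WT", "AD+"), sex = c("M", "F"),
                             age_months = 8.5, condition = "E") {
  stopifnot(inherits(params, "exploration_params"))
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  conf <- confusion_matrix(params)
  dur <- params$duration_s
  # the renewal time process is drawn before the arm choices, so sessions
  # sharing a seed have identical entry counts and times whatever the
  # preference/memory/discriminability settings
  ev <- local_seed(seed, {
    t_enter <- 0
    repeat {
      nxt_t <- t_enter[length(t_enter)] +
        stats::rexp(1, rate = params$entry_rate / 60)
      if (nxt_t > dur) break
      t_enter <- c(t_enter, nxt_t)
    }
    n <- length(t_enter)
    dwell <- stats::rexp(n, rate = 1 / params$dwell_mean)
    gap_limit <- c(diff(t_enter), dur - t_enter[n])
    t_exit <- t_enter + pmin(dwell, gap_limit)
    arms <- character(n)
    arms[1L] <- sample(params$labels, 1L,
                       prob = params$preference / sum(params$preference))
    if (n > 1L) {
      for (i in 2:n) {
        mem <- arms[max(1L, i - params$memory_span):(i - 1L)]
        arms[i] <- draw_next_arm(params, mem, conf)
      }
    }
    data.frame(arm = arms, t_enter = t_enter, t_exit = pmin(t_exit, dur))
  })
  session(mouse_id, ev, genotype = genotype, sex = sex,
          age_months = age_months, condition = condition,
          duration_s = dur, mode = "color")
}

#' Simulate a cohort of sessions across groups
#'
#' @param group_specs Named list of group specifications, each a list with
#'   `params` (an [exploration_params()]) and optional metadata fields
#'   `genotype`, `sex`, `age_months`, `condition`.
#' @param n_per_group Sessions per group (>= 1; recycled across groups).
#' @param seed Integer seed; each session gets a distinct derived seed, so
#'   the same seed reproduces the cohort exactly.
#' @return List of [session()] objects with mouse ids `<group>_<i>`.
#' @export
simulate_cohort <- function(group_specs, n_per_group, seed) {
  stopifnot(is.list(group_specs), length(group_specs) >= 1L,
            !is.null(names(group_specs)))
  n_per_group <- rep_len(n_per_group, length(group_specs))
  if (any(n_per_group < 1L)) stop("n_per_group must be at least 1")
  sessions <- list()
  counter <- 0L
  for (g in seq_along(group_specs)) {
    spec <- group_specs[[g]]
    gname <- names(group_specs)[g]
    for (i in seq_len(n_per_group[g])) {
      counter <- counter + 1L
      sessions[[counter]] <- simulate_session(
        spec$params, seed = (seed + 7919L * counter) %% .Machine$integer.max,
        mouse_id = sprintf("%s_%02d", gname, i),
        genotype = spec$genotype %||% "WT",
        sex = spec$sex %||% "M",
        age_months = spec$age_months %||% 8.5,
        condition = spec$condition %||% "E"
      )
    }
  }
  sessions
}
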