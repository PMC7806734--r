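test_that("parameter constructors validate their inputs", {
  p <- exploration_params()
  expect_s3_class(p, "exploration_params")
  expect_equal(unname(p$discriminability), rep(1, 6))
  expect_error(exploration_params(memory_strength = 1.2), "memory_strength")
  expect_error(exploration_params(discriminability = c("B:Q" = 0.5)),
               "unknown pair")
  expect_error(exploration_params(entry_rate = 0), "entry_rate")
})

test_that("sessions are deterministic given a seed and structurally valid", {
  p <- exploration_preset("WT")
  s1 <- simulate_session(p, seed = 7)
  s2 <- simulate_session(p, seed = 7)
  expect_identical(s1$events, s2$events)
  expect_false(identical(s1$events, simulate_session(p, seed = 8)$events))
  ev <- s1$events
  expect_true(all(ev$t_exit >= ev$t_enter))
  expect_true(all(ev$t_enter >= 0 & ev$t_exit <= s1$duration_s))
  expect_false(is.unsorted(ev$t_enter))
  # cohorts reproduce byte-identically under the same seed
  specs <- list(wt = list(params = p, genotype = "WT"))
  c1 <- simulate_cohort(specs, 3, seed = 5)
  c2 <- simulate_cohort(specs, 3, seed = 5)
  expect_identical(lapply(c1, `[[`, "events"), lapply(c2, `[[`, "events"))
  expect_error(simulate_cohort(specs, 0, seed = 1), "at least 1")
})

test_that("memoryless uniform parameters reproduce the analytic null", {
  p0 <- exploration_params(memory_strength = 0)
  seq <- simulate_arm_sequence(p0, 20000, seed = 17)
  expect_false(any(seq[-1] == seq[-length(seq)]))
  counts <- transition_profile(seq)$uni_counts
  # chi-squared goodness of fit against uniform 1/12
  chisq <- sum((counts - sum(counts) / 12)^2 / (sum(counts) / 12))
  expect_gt(pchisq(chisq, df = 11, lower.tail = FALSE), 0.01)
  # mean alternation across short null sessions matches the expectation
  alts <- vapply(1:800, function(i) {
    percent_alternation(simulate_arm_sequence(p0, 30, seed = 100 + i))$percent
  }, numeric(1))
  se <- sd(alts) / sqrt(length(alts))
  expect_lt(abs(mean(alts) - expected_alternation_percent(30)), 3 * se)
})

test_that("perfect memory and avoidance force near-maximal alternation", {
  p1 <- exploration_params(memory_strength = 1, avoidance = 0)
  for (seed in 1:5) {
    seq <- simulate_arm_sequence(p1, 30, seed = seed)
    expect_equal(percent_alternation(seq)$percent, 100 * 27 / 28,
                 tolerance = 1e-12)
  }
})

test_that("alternation is monotone in memory strength and avoidance", {
  mean_alt <- function(params) {
    mean(vapply(1:150, function(i) {
      percent_alternation(simulate_arm_sequence(params, 30, seed = i))$percent
    }, numeric(1)))
  }
  by_m <- vapply(c(0, 0.5, 1), function(m) {
    mean_alt(exploration_params(memory_strength = m, avoidance = 0.1))
  }, numeric(1))
  expect_true(all(diff(by_m) > 0))
  by_eps <- vapply(c(0, 0.5, 1), function(e) {
    mean_alt(exploration_params(memory_strength = 0.9, avoidance = e))
  }, numeric(1))
  expect_true(all(diff(by_eps) < 0))
})

test_that("low pair discriminability selectively collapses that pair's transitions", {
  # strong-memory regime where avoidance (and hence its confusion-driven
  # misdirection) carries most of the choice signal
  ctrl <- exploration_params(memory_strength = 0.9, avoidance = 0.05)
  impaired <- exploration_params(memory_strength = 0.9, avoidance = 0.05,
                                 discriminability = c("B:W" = 0.2))
  bw <- function(params, seed) {
    s <- simulate_arm_sequence(params, 40, seed = seed)
    transition_profile(s)$bi_percent["B:W"]
  }
  diff_bw <- vapply(1:1000, function(s) bw(impaired, s) - bw(ctrl, s),
                    numeric(1))
  expect_lt(t.test(diff_bw, alternative = "less")$p.value, 0.01)
})

test_that("discriminability does not alter total entries (paired seeds)", {
  ctrl <- exploration_preset("WT")
  impaired <- exploration_params(
    preference = ctrl$preference, memory_strength = ctrl$memory_strength,
    avoidance = ctrl$avoidance, discriminability = c("B:W" = 0.2),
    entry_rate = ctrl$entry_rate, dwell_mean = ctrl$dwell_mean
  )
  for (seed in c(3, 14, 27)) {
    a <- simulate_session(ctrl, seed = seed)
    b <- simulate_session(impaired, seed = seed)
    expect_identical(nrow(a$events), nrow(b$events))
    expect_equal(a$events$t_enter, b$events$t_enter)
  }
})

test_that("presets emulate the intended cohort phenotypes", {
  mean_alt <- function(preset, genotype) {
    specs <- list(g = list(params = preset, genotype = genotype))
    sess <- simulate_cohort(specs, 16, seed = 42)
    alts <- vapply(sess, function(s) {
      seq <- arm_sequence(s)
      if (length(seq) < 4) NA_real_ else percent_alternation(seq)$percent
    }, numeric(1))
    mean(alts, na.rm = TRUE)
  }
  wt <- mean_alt(exploration_preset("WT"), "WT")
  ad <- mean_alt(exploration_preset("AD"), "AD+")
  expect_gt(wt, 40)                      # wild-type range
  expect_gt(ad, 10); expect_lt(ad, 35)   # near-chance transgenic range
  expect_gt(wt, ad)
})

test_that("step likelihood sums to one and matches empirical choice frequencies", {
  p <- exploration_params(memory_strength = 0.7, avoidance = 0.3,
                          discriminability = c("B:W" = 0.4))
  conf <- vis4m:::confusion_matrix(p)
  for (mem in list("R", c("R", "G"), c("W", "B", "W"))) {
    pr <- vis4m:::choice_prob_given_memory(p, mem, conf)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
  # empirical frequencies from the sampler agree with the analytic step law
  pr <- vis4m:::choice_prob_given_memory(p, c("W", "B", "W"), conf)
  draws <- withr::with_seed(5, {
    replicate(4000, vis4m:::draw_next_arm(p, c("W", "B", "W"), conf))
  })
  emp <- table(factor(draws, levels = names(pr))) / length(draws)
  expect_true(all(abs(as.vector(emp) - pr) <
                    3 * sqrt(pr * (1 - pr) / 4000) + 0.005))
})

test_that("maximum likelihood recovers a reduced pair discriminability", {
  true <- exploration_params(memory_strength = 0.9, avoidance = 0.1,
                             discriminability = c("B:W" = 0.3))
  base <- exploration_params(memory_strength = 0.9, avoidance = 0.1)
  seqs <- lapply(1:80, function(i) simulate_arm_sequence(true, 30, seed = i))
  fit <- fit_exploration_params(seqs, base, "B:W", true_params = true)
  expect_lt(abs(fit$estimate - 0.3), 0.12)
  expect_lte(fit$ci_lo, fit$estimate)
  expect_gte(fit$ci_hi, fit$estimate)
  expect_equal(fit$true, 0.3)
})

test_that("memory strength fitted on null data shrinks to zero", {
  base <- exploration_params(memory_strength = 0.5, avoidance = 0.2)
  seqs <- lapply(1:100, function(i) simulate_null_sequence(30, seed = 500 + i))
  fit <- fit_exploration_params(seqs, base, "memory_strength")
  expect_lt(fit$estimate, 0.15)
})

test_that("the likelihood prefers the generating parameters on average", {
  true <- exploration_params(memory_strength = 0.8, avoidance = 0.2)
  worse <- exploration_params(memory_strength = 0.3, avoidance = 0.2)
  diffs <- vapply(1:30, function(r) {
    seqs <- lapply(1:10, function(i) {
      simulate_arm_sequence(true, 30, seed = r * 100 + i)
    })
    counts <- vis4m:::context_counts(seqs, true$memory_span)
    vis4m:::neg_log_likelihood(worse, counts) -
      vis4m:::neg_log_likelihood(true, counts)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("underdetermined fits warn instead of failing silently", {
  base <- exploration_params()
  seqs <- list(simulate_null_sequence(5, seed = 1))
  expect_warning(fit_exploration_params(seqs, base, "memory_strength"),
                 "few observed choices")
})
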