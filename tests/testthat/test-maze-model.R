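test_that("collapse_reentries performs run-length reduction and is idempotent", {
  cases <- list(
    list(input = c("R", "R", "G", "B"), out = c("R", "G", "B"), n = 1L),
    list(input = c("R", "G", "B", "W"), out = c("R", "G", "B", "W"), n = 0L),
    list(input = c("R", "R", "R", "G", "G"), out = c("R", "G"), n = 3L)
  )
  for (cs in cases) {
    got <- collapse_reentries(cs$input)
    expect_identical(got$sequence, cs$out)
    expect_identical(got$n_collapsed, cs$n)
    again <- collapse_reentries(got$sequence)
    expect_identical(again$sequence, got$sequence)
    expect_identical(again$n_collapsed, 0L)
  }
  empty <- collapse_reentries(character(0))
  expect_identical(empty$sequence, character(0))
  expect_identical(empty$n_collapsed, 0L)
})

test_that("percent_alternation scores sliding windows against the N-2 denominator", {
  r <- percent_alternation(c("R", "G", "B", "W"))
  expect_identical(r$n_successes, 1L)
  expect_equal(r$percent, 50)

  expect_equal(percent_alternation(c("R", "G", "R", "G", "R", "G"))$percent, 0)

  seq9 <- c("B", "W", "R", "G", "B", "G", "W", "R", "B")
  r9 <- percent_alternation(seq9)
  expect_identical(r9$n_successes, 4L)
  expect_equal(r9$percent, 100 * 4 / 7, tolerance = 1e-12)
  expect_equal(round(r9$percent, 1), 57.1)
  expect_equal(r9$percent, oracle_alternation_percent(seq9))

  # windows-denominator variant: a perfect sequence reaches 100
  expect_equal(percent_alternation(rep(c("R", "G", "B", "W"), 5),
                                   denominator = "windows")$percent, 100)
})

test_that("alternation errors on short or uncollapsed input", {
  expect_error(percent_alternation(c("R", "G", "B")), "too short")
  expect_error(percent_alternation(c("R", "R", "G", "B")), "consecutive")
})

test_that("percent_alternation matches the brute-force window oracle on random sequences", {
  withr::with_seed(42, {
    for (i in 1:300) {
      n <- sample(4:50, 1)
      seq <- random_arm_sequence(n)
      expect_equal(percent_alternation(seq)$percent,
                   oracle_alternation_percent(seq))
      # cap: never above 100 (N-3)/(N-2), reached iff all windows distinct
      cap <- 100 * (n - 3) / (n - 2)
      expect_lte(percent_alternation(seq)$percent, cap + 1e-12)
    }
  })
})

test_that("percent_entries counts raw entries and sums to 100", {
  expect_equal(unname(percent_entries(c("R", "G", "B", "W"))),
               rep(25, 4))
  pe <- percent_entries(c("R", "R", "R", "G"), labels = c("B", "G", "R", "W"))
  expect_equal(unname(pe[c("R", "G", "B", "W")]), c(75, 25, 0, 0))
  seq9 <- c("B", "W", "R", "G", "B", "G", "W", "R", "B")
  pe9 <- percent_entries(seq9)
  expect_equal(unname(pe9["B"]), 100 * 3 / 9, tolerance = 1e-12)
  expect_equal(unname(pe9["W"]), 100 * 2 / 9, tolerance = 1e-12)
  expect_equal(sum(pe9), 100, tolerance = 1e-9)
  expect_error(percent_entries(character(0)), "empty")
})

test_that("percent_time uses in-arm dwell with center time excluded", {
  ev <- data.frame(arm = c("B", "G", "R", "W"),
                   t_enter = c(0, 20, 50, 90),
                   t_exit = c(10, 40, 80, 130))
  pt <- percent_time(ev)
  expect_equal(unname(pt), c(10, 20, 30, 40))
  expect_equal(sum(pt), 100)

  one <- data.frame(arm = "R", t_enter = 0, t_exit = 300)
  expect_equal(unname(percent_time(one, labels = c("B", "G", "R", "W"))["R"]),
               100)

  mixed <- data.frame(arm = c("R", "G", "B", "W"),
                      t_enter = c(0, 50, 70, 90),
                      t_exit = c(45, 65, 85, 165))
  expect_equal(unname(percent_time(mixed)[c("R", "G", "B", "W")]),
               c(30, 10, 10, 50))

  zero <- data.frame(arm = "R", t_enter = 5, t_exit = 5)
  expect_error(percent_time(zero), "zero total dwell")
})

test_that("transition_profile tallies the 12 ordered and 6 unordered types", {
  p <- transition_profile(c("R", "G", "B", "W", "R"))
  expect_length(p$uni_counts, 12L)
  expect_length(p$bi_percent, 6L)
  expect_equal(p$total_transitions, 4L)
  expect_equal(unname(p$uni_percent[c("R>G", "G>B", "B>W", "W>R")]),
               rep(25, 4))
  expect_equal(sum(p$uni_percent), 100)

  p2 <- transition_profile(c("R", "G", "R", "G"))
  expect_equal(unname(p2$uni_percent["R>G"]), 200 / 3, tolerance = 1e-12)
  expect_equal(unname(p2$uni_percent["G>R"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(p2$bi_percent["G:R"]), 100, tolerance = 1e-12)

  seq9 <- c("B", "W", "R", "G", "B", "G", "W", "R", "B")
  p9 <- transition_profile(seq9)
  expect_equal(p9$total_transitions, 8L)
  expect_equal(unname(p9$uni_percent["W>R"]), 25)
  expect_equal(unname(p9$uni_percent["B>W"]), 12.5)
  expect_equal(unname(p9$bi_percent["R:W"]), 25)
  expect_equal(unname(p9$bi_percent["B:G"]), 25)

  expect_error(transition_profile("R"), "no transitions")
})

test_that("transition percentages match a direct tally and bi = sum of uni", {
  withr::with_seed(7, {
    for (i in 1:100) {
      seq <- random_arm_sequence(sample(2:60, 1))
      p <- transition_profile(seq)
      tab <- oracle_uni_counts(seq)
      expect_equal(unname(p$uni_counts[names(tab)]),
                   as.integer(tab))
      expect_equal(sum(p$uni_counts), length(seq) - 1L)
      expect_equal(sum(p$uni_percent), 100, tolerance = 1e-9)
      up <- unordered_arm_pairs()
      for (j in seq_len(nrow(up))) {
        expect_identical(
          unname(p$bi_percent[up$pair[j]]),
          unname(p$uni_percent[paste0(up$a[j], ">", up$b[j])] +
                   p$uni_percent[paste0(up$b[j], ">", up$a[j])])
        )
      }
    }
  })
})

test_that("quartile selection takes top/bottom 3 with canonical tie-break", {
  # distinct ranks: Q4 = the three largest
  seq <- c("R", "G", "B", "W", "R")
  p <- transition_profile(seq)
  # synthetic profile with values 1..12 in canonical order
  p12 <- p
  p12$uni_percent[] <- seq_len(12)
  expect_setequal(select_quartile_transitions(p12, "Q4_most_frequent"),
                  names(p12$uni_percent)[10:12])
  expect_setequal(select_quartile_transitions(p12, "Q1_least_frequent"),
                  names(p12$uni_percent)[1:3])

  # all equal: first three canonical pairs
  peq <- p
  peq$uni_percent[] <- 100 / 12
  expect_identical(select_quartile_transitions(peq, "Q4_most_frequent"),
                   c("B>G", "B>R", "B>W"))

  # worked sequence: W>R leads at 25%, ties at 12.5% broken canonically
  p9 <- transition_profile(c("B", "W", "R", "G", "B", "G", "W", "R", "B"))
  expect_identical(select_quartile_transitions(p9, "Q4_most_frequent"),
                   c("W>R", "B>G", "B>W"))
})

test_that("maze layout partitions the arms into two facing pairs", {
  ml <- maze_layout("color")
  expect_setequal(unlist(ml$facing_pairs), arm_labels("color"))
  expect_true(all(c("B", "G") %in% ml$facing_pairs[[1]]))
  expect_error(maze_layout("color", facing_pairs = list(c("B", "G"),
                                                        c("B", "W"))),
               "partition")
})
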